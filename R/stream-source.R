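## The reading stage: iteratively follow one or two growing files, extract
## only complete records (pairs), enforce a per-iteration byte cap, split the
## extracted records across parallel readers deterministically, and stamp
## every chunk with (iteration, worker) for global ordering.

#' Dynamic reader count for one iteration
#'
#' The number of parallel readers adapts to how much data is available, so
#' that many readers are not spawned for little data:
#' `clamp(ceiling(availableBytes / minBytesPerWorker), 1, maxWorkers)`.
#' Deterministic for a fixed configuration, which chunk stamping (and hence
#' reproducible output order) relies on.
#'
#' @param availableBytes bytes of new data available this iteration (>= 0).
#' @param minBytesPerWorker bytes that justify one reader (default 4 MiB).
#' @param maxWorkers upper clamp (default: CPU count).
#' @return integer worker count in `[1, maxWorkers]`.
#' @examples
#' chooseWorkers(0)                                   # 1
#' chooseWorkers(10 * 4^10 * 4, maxWorkers = 4)       # clamped to 4
#' @export
chooseWorkers <- function(availableBytes,
                          minBytesPerWorker = 4 * 1024^2,
                          maxWorkers = parallel::detectCores()) {
    stopifnot(availableBytes >= 0, minBytesPerWorker > 0, maxWorkers >= 1)
    max(1L, min(as.integer(maxWorkers),
                as.integer(ceiling(availableBytes / minBytesPerWorker))))
}

## contiguous order-preserving split of n records into w slices; worker 1
## gets the earliest records (and any remainder goes to the earliest slices)
chunkSlices <- function(n, w) {
    w <- max(1L, min(w, n))
    sizes <- rep(n %/% w, w)
    extra <- n %% w
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    Map(seq.int, starts, ends)
}

#' Open a stream source over one or two sequence files
#'
#' Creates the follower state for a file (or a pair of mate files) that may
#' still be growing on disk. [pollSource()] then extracts newly completed
#' records iteration by iteration. gzip-compressed inputs are supported only
#' as complete files (use [readSeqFile()] or a no-follow run): re-scanning a
#' growing compressed stream is not well-defined.
#'
#' @param path input file (mate 1 in paired mode).
#' @param path2 optional mate 2 file; enables paired mode.
#' @param format `"auto"`, `"fastq"` or `"fasta"`; auto-detection reads the
#'   first byte (both mates must agree).
#' @param capBytes per-iteration cap on newly read bytes per file
#'   (default 64 MiB). Bounds memory and keeps reading overlapped with
#'   processing.
#' @param minBytesPerWorker,maxWorkers see [chooseWorkers()].
#' @return A [StreamSource-class] object.
#' @export
newStreamSource <- function(path, path2 = NULL, format = "auto",
                            capBytes = 64 * 1024^2,
                            minBytesPerWorker = 4 * 1024^2,
                            maxWorkers = parallel::detectCores()) {
    paths <- c(path, path2)
    for (p in paths)
        if (!file.exists(p))
            stopQC("streamqc_io_error", "no such file: '%s'", p)
    if (format == "auto") {
        fmts <- vapply(paths, detectFormat, character(1L))
        if (length(unique(fmts)) > 1L)
            stopQC("streamqc_pair_error",
                   "paired files have different formats: %s vs %s",
                   fmts[1L], fmts[2L])
        format <- fmts[1L]
    }
    format <- match.arg(format, c("fastq", "fasta"))
    paired <- length(paths) == 2L
    new("StreamSource", paths = paths, format = format, paired = paired,
        committed = rep(0, length(paths)),
        carry = rep(list(raw(0L)), length(paths)),
        pending = if (paired) rep(list(SeqRecords(format = format)), 2L)
                  else list(),
        iteration = 1L, finished = FALSE,
        capBytes = as.numeric(capBytes),
        minBytesPerWorker = as.numeric(minBytesPerWorker),
        maxWorkers = as.integer(maxWorkers))
}

## read up to capBytes new bytes of file k beyond committed+carry
readNewBytes <- function(state, k) {
    path <- state@paths[k]
    fsize <- file.size(path)
    pos <- state@committed[k] + length(state@carry[[k]])
    if (is.na(fsize) || fsize < pos)
        stopQC("streamqc_io_error",
               "source file '%s' shrank (%.0f < %.0f bytes): corrupted source",
               path, fsize, pos)
    toRead <- min(state@capBytes, fsize - pos)
    newBytes <- raw(0L)
    if (toRead > 0) {
        con <- file(path, "rb")
        on.exit(close(con))
        seek(con, where = pos, origin = "start")
        newBytes <- readBin(con, "raw", n = toRead)
    }
    list(newBytes = newBytes, eof = (pos + length(newBytes)) >= fsize)
}

## scan one file's buffer; returns records + updated committed/carry
scanFileOnce <- function(state, k, atEnd) {
    rd <- readNewBytes(state, k)
    buffer <- c(state@carry[[k]], rd$newBytes)
    scanAtEnd <- atEnd && rd$eof
    res <- scanRecords(buffer, state@format, atEnd = scanAtEnd)
    consumed <- res$consumedBytes
    list(records = res$records,
         committed = state@committed[k] + consumed,
         carry = if (consumed < length(buffer))
             buffer[(consumed + 1L):length(buffer)] else raw(0L),
         eof = rd$eof, drained = scanAtEnd && consumed == length(buffer),
         newByteCount = length(rd$newBytes))
}

stampChunks <- function(state, records, availableBytes, second = NULL) {
    n <- length(records)
    if (n == 0L) return(list())
    w <- chooseWorkers(availableBytes, state@minBytesPerWorker,
                       state@maxWorkers)
    slices <- chunkSlices(n, w)
    lapply(seq_along(slices), function(j)
        Chunk(state@iteration, j, records[slices[[j]]],
              if (!is.null(second)) second[slices[[j]]]))
}

#' Poll a stream source for newly completed records
#'
#' One iteration of the reading stage. At most `capBytes` new bytes per file
#' are read beyond what was already consumed; only complete records are
#' extracted (a trailing incomplete record's bytes stay in the carry buffer
#' until more data arrives). Extracted records are split into contiguous,
#' order-preserving slices across `w = chooseWorkers(...)` readers and
#' stamped `(iteration, 1..w)`; the iteration counter advances only when at
#' least one chunk was produced, so stamps are dense.
#'
#' In paired mode both files are scanned independently, then only
#' `min(n1, n2)` pairs are emitted (the i-th record of file 1 with the i-th
#' of file 2, kept together in the same chunk); surplus complete records of
#' the faster file wait in a pending queue for a later iteration. If the
#' stream ends with unequal totals, an unpaired trailing record error is
#' raised.
#'
#' @param state a [StreamSource-class].
#' @param atEnd logical: has the end-of-input condition been declared (no
#'   more growth expected)? Only then may the final FASTA record -- and a
#'   final FASTQ record missing its trailing newline -- be emitted, and only
#'   then can the source reach `finished`.
#' @return `list(chunks = <list of Chunk>, state = <updated StreamSource>)`.
#' @seealso [newStreamSource()], [runStream()]
#' @export
pollSource <- function(state, atEnd = FALSE) {
    stopifnot(is(state, "StreamSource"))
    if (state@finished)
        return(list(chunks = list(), state = state))
    if (state@paired) pollIterationPaired(state, atEnd)
    else pollIteration(state, atEnd)
}

#' @rdname pollSource
#' @export
pollIteration <- function(state, atEnd = FALSE) {
    sc <- scanFileOnce(state, 1L, atEnd)
    chunks <- stampChunks(state, sc$records,
                          length(state@carry[[1L]]) + sc$newByteCount)
    state@committed[1L] <- sc$committed
    state@carry[[1L]] <- sc$carry
    if (length(chunks) > 0L) state@iteration <- state@iteration + 1L
    if (sc$drained) state@finished <- TRUE
    list(chunks = chunks, state = state)
}

#' @rdname pollSource
#' @export
pollIterationPaired <- function(state, atEnd = FALSE) {
    sc1 <- scanFileOnce(state, 1L, atEnd)
    sc2 <- scanFileOnce(state, 2L, atEnd)
    p1 <- c(state@pending[[1L]], sc1$records)
    p2 <- c(state@pending[[2L]], sc2$records)
    npair <- min(length(p1), length(p2))
    first <- p1[seq_len(npair)]
    second <- p2[seq_len(npair)]
    rest1 <- p1[seq_len(length(p1) - npair) + npair]
    rest2 <- p2[seq_len(length(p2) - npair) + npair]
    avail <- length(state@carry[[1L]]) + sc1$newByteCount +
        length(state@carry[[2L]]) + sc2$newByteCount
    chunks <- stampChunks(state, first, avail, second = second)
    state@committed <- c(sc1$committed, sc2$committed)
    state@carry <- list(sc1$carry, sc2$carry)
    state@pending <- list(rest1, rest2)
    if (length(chunks) > 0L) state@iteration <- state@iteration + 1L
    if (sc1$drained && sc2$drained) {
        if (length(rest1) != length(rest2))
            stopQC("streamqc_pair_error",
                   paste0("paired inputs ended with unequal record counts: ",
                          "%d unpaired trailing record(s) in %s"),
                   abs(length(rest1) - length(rest2)),
                   state@paths[if (length(rest1) > length(rest2)) 1L else 2L])
        state@finished <- TRUE
    }
    list(chunks = chunks, state = state)
}

## subfile spooling -------------------------------------------------------

#' Spool a chunk to disk as a "subfile"
#'
#' Serializes a chunk the way the streaming reader hands batches to the
#' processing engine: each record (or pair, written consecutively) is
#' preceded by a separator line holding a token that cannot occur inside
#' records (default: the ASCII record-separator character 0x1E), making
#' record boundaries unambiguous even though `@` may open a quality line.
#' The file name encodes the stamp. Spooling is optional debugging/fidelity
#' plumbing -- the engine passes chunks in memory.
#'
#' @param chunk a [Chunk-class].
#' @param dir writable spool directory.
#' @param sep separator token (single line content).
#' @return The subfile path, invisibly.
#' @seealso [loadChunk()]
#' @export
spoolChunk <- function(chunk, dir, sep = "\x1e") {
    stopifnot(is(chunk, "Chunk"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (chunk@first@format == "fastq") "fq" else "fa"
    path <- file.path(dir, sprintf("subfile-%06d-%06d%s.%s",
                                   chunk@iteration, chunk@worker,
                                   if (chunk@paired) "-paired" else "", ext))
    sepLine <- charToRaw(paste0(sep, "\n"))
    n <- length(chunk@first)
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
        rec <- writeRecords(chunk@first[i])
        if (chunk@paired) rec <- c(rec, writeRecords(chunk@second[i]))
        pieces[[i]] <- c(sepLine, rec)
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(do.call(c, c(pieces, list(raw(0L)))), con)
    invisible(path)
}

#' Load a spooled subfile back into a Chunk
#'
#' Inverse of [spoolChunk()]: the stamp and pairing layout are recovered
#' from the file name, the separator lines are dropped, and the records are
#' re-parsed. Round-trips the chunk payload and stamp exactly.
#'
#' @param path subfile written by [spoolChunk()].
#' @param sep separator token used when spooling.
#' @return A [Chunk-class].
#' @export
loadChunk <- function(path, sep = "\x1e") {
    m <- regmatches(basename(path),
                    regexec("^subfile-([0-9]{6})-([0-9]{6})(-paired)?\\.f[qa]$",
                            basename(path)))[[1L]]
    if (length(m) == 0L)
        stopQC("streamqc_io_error", "not a subfile name: '%s'", basename(path))
    iteration <- as.integer(m[2L]); worker <- as.integer(m[3L])
    paired <- nzchar(m[4L])
    format <- if (grepl("\\.fq$", path)) "fastq" else "fasta"
    lines <- readLines(path)
    lines <- lines[lines != sep]
    recs <- if (length(lines) == 0L) SeqRecords(format = format)
        else scanRecords(paste0(paste0(lines, collapse = "\n"), "\n"),
                         format, atEnd = TRUE)$records
    if (paired) {
        odd <- seq_along(recs) %% 2L == 1L
        Chunk(iteration, worker, recs[odd], recs[!odd])
    } else Chunk(iteration, worker, recs)
}
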