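## Seeded synthetic datasets and a throttled slow-writer that emulates an
## in-progress download, including deliberate mid-record cuts and asymmetric
## paired download rates. Everything is deterministic for a fixed seed.

PHRED_CHARS <- vapply(0:93, function(s) rawToChar(as.raw(s + 33L)),
                      character(1L))

buildStrings <- function(charMatrix, lens) {
    s <- do.call(paste0, lapply(seq_len(ncol(charMatrix)),
                                function(j) charMatrix[, j]))
    substr(s, 1L, lens)
}

#' Generate a synthetic sequencing dataset
#'
#' Writes `n` reads with uniform-random ACGT bases and per-base Phred+33
#' quality scores drawn from a rounded normal distribution truncated to
#' `qualityRange` (defaults emulate a short-read run: 76 bp reads, mean
#' quality 35 on the 2--40 scale). An optional per-base non-IUPAC injection
#' rate replaces bases with `X` to exercise the `noniupac` filter. Fully
#' deterministic for a fixed seed: the same call produces byte-identical
#' files. Identifiers are `<idPrefix><i>` (with `/1`, `/2` mate suffixes in
#' paired mode, positionally matched across the two files).
#'
#' @param n number of reads (>= 0).
#' @param path output file (mate 1 in paired mode).
#' @param path2 optional mate 2 output; enables paired mode.
#' @param format `"fastq"` or `"fasta"`.
#' @param readLength single length, or `c(min, max)` for uniform per-read
#'   lengths.
#' @param qualityMean,qualitySd per-base quality score distribution.
#' @param qualityRange inclusive truncation bounds for quality scores.
#' @param nonIupacRate per-base probability of replacement with `X`.
#' @param seed integer seed fixing all randomness.
#' @param idPrefix identifier prefix.
#' @return The output path(s), invisibly.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' generateReads(10, f, readLength = 20, seed = 7)
#' readSeqFile(f)
#' @export
generateReads <- function(n, path, path2 = NULL, format = "fastq",
                          readLength = 76, qualityMean = 35,
                          qualitySd = 6, qualityRange = c(2, 40),
                          nonIupacRate = 0, seed = 1, idPrefix = "read") {
    stopifnot(n >= 0, length(readLength) %in% 1:2, all(readLength >= 0),
              nonIupacRate >= 0, nonIupacRate <= 1,
              qualityRange[1] <= qualityRange[2], qualityRange[1] >= 0,
              qualityRange[2] <= 93)
    format <- match.arg(format, c("fastq", "fasta"))
    paired <- !is.null(path2)
    paths <- c(path, path2)
    withr::with_seed(as.integer(seed), {
        for (mate in seq_along(paths)) {
            if (n == 0L) {
                writeSeqFile(SeqRecords(format = format), paths[mate])
                next
            }
            maxLen <- max(readLength)
            lens <- if (length(readLength) == 2L)
                sample(readLength[1]:readLength[2], n, replace = TRUE)
            else rep(as.integer(readLength), n)
            m <- matrix(sample(c("A", "C", "G", "T"), n * maxLen,
                               replace = TRUE), nrow = n)
            if (nonIupacRate > 0) {
                hit <- stats::runif(n * maxLen) < nonIupacRate
                m[hit] <- "X"
            }
            bases <- buildStrings(m, lens)
            ids <- paste0(idPrefix, seq_len(n),
                          if (paired) paste0("/", mate) else "")
            if (format == "fastq") {
                sc <- pmin(pmax(round(stats::rnorm(n * maxLen, qualityMean,
                                                   qualitySd)),
                                qualityRange[1]), qualityRange[2])
                qm <- matrix(PHRED_CHARS[sc + 1L], nrow = n)
                qual <- buildStrings(qm, lens)
                writeSeqFile(SeqRecords(ids, bases, qual), paths[mate])
            } else {
                writeSeqFile(SeqRecords(ids, bases, format = "fasta"),
                             paths[mate])
            }
        }
    })
    invisible(paths)
}

#' Create a slow writer that grows a copy of a file incrementally
#'
#' Returns a stepper object emulating an in-progress download of `src` into
#' `dest`: each `$step()` appends the next increment of a seeded schedule
#' of byte counts; `dest` grows monotonically and, after the last step,
#' equals `src` byte for byte. With `cutMidRecord = TRUE` (default) the
#' increments are uniform random byte counts in `[1, 2 * bytesPerTick]`,
#' which deliberately split records anywhere -- including between a FASTQ
#' `+` line and a quality line beginning with `@`; with
#' `cutMidRecord = FALSE` increments are aligned to record boundaries.
#'
#' The stepper exposes `$step()` (append next increment; returns bytes
#' written, 0 when complete), `$finished()`, `$schedule` (the cumulative
#' offsets after each step) and `$size`.
#'
#' @param src complete source file.
#' @param dest destination file (created empty).
#' @param bytesPerTick mean increment size in bytes.
#' @param cutMidRecord allow increments to end mid-record.
#' @param seed integer seed fixing the schedule.
#' @param format record format of `src`, needed only for
#'   `cutMidRecord = FALSE` boundary alignment (`"auto"` detects).
#' @return The stepper (an environment), invisibly classed
#'   `"slowWriter"`.
#' @seealso [slowWrite()] for a real-time loop over the stepper.
#' @export
slowWriter <- function(src, dest, bytesPerTick = 4096, cutMidRecord = TRUE,
                       seed = 1, format = "auto") {
    if (!file.exists(src))
        stopQC("streamqc_io_error", "no such file: '%s'", src)
    size <- file.size(src)
    offsets <- if (cutMidRecord) {
        withr::with_seed(as.integer(seed), {
            sizes <- integer(0)
            while (sum(sizes) < size)
                sizes <- c(sizes, sample.int(max(2L * round(bytesPerTick),
                                                 2L), 64L, replace = TRUE))
            cum <- cumsum(as.numeric(sizes))
            cum[cum < size]
        })
    } else {
        if (format == "auto") format <- detectFormat(src)
        con <- file(src, "rb")
        buf <- readBin(con, "raw", n = size)
        close(con)
        ## record end offsets: scan prefix-complete records
        res <- scanRecords(buf, format, atEnd = TRUE)$records
        piece <- writeRecords(res[1L])
        bnd <- cumsum(vapply(seq_len(length(res)), function(i)
            length(writeRecords(res[i])), numeric(1L)))
        ## serialized boundaries only match byte offsets for canonical
        ## input; fall back to newline-aligned offsets otherwise
        if (length(bnd) == 0L || bnd[length(bnd)] != size)
            bnd <- which(buf == as.raw(10L))
        withr::with_seed(as.integer(seed), {
            out <- numeric(0); pos <- 0
            while (pos < size) {
                target <- pos + max(1, round(bytesPerTick *
                                             stats::runif(1, 0.5, 1.5)))
                nxt <- bnd[bnd >= target]
                pos <- if (length(nxt)) nxt[1L] else size
                out <- c(out, pos)
            }
            out[out < size]
        })
    }
    offsets <- c(offsets, size)
    file.create(dest)
    env <- new.env(parent = emptyenv())
    env$src <- src; env$dest <- dest; env$size <- size
    env$schedule <- offsets
    env$i <- 0L
    env$written <- 0
    env$step <- function() {
        if (env$i >= length(env$schedule)) return(0L)
        env$i <- env$i + 1L
        upto <- env$schedule[env$i]
        nb <- upto - env$written
        con <- file(env$src, "rb")
        seek(con, where = env$written, origin = "start")
        bytes <- readBin(con, "raw", n = nb)
        close(con)
        out <- file(env$dest, "ab")
        writeBin(bytes, out)
        close(out)
        env$written <- upto
        as.integer(nb)
    }
    env$finished <- function() env$i >= length(env$schedule)
    class(env) <- "slowWriter"
    invisible(env)
}

#' @export
print.slowWriter <- function(x, ...) {
    cat(sprintf("slowWriter: %s -> %s, %.0f/%.0f bytes in %d/%d step(s)\n",
                x$src, x$dest, x$written, x$size, x$i, length(x$schedule)))
    invisible(x)
}

#' Copy a file slowly, emulating a throttled download
#'
#' Real-time convenience loop over [slowWriter()]: appends one increment
#' every `tick` seconds until `dest` equals `src`.
#'
#' @inheritParams slowWriter
#' @param tick seconds between increments.
#' @return `dest`, invisibly.
#' @export
slowWrite <- function(src, dest, bytesPerTick = 4096, tick = 0.05,
                      cutMidRecord = TRUE, seed = 1, format = "auto") {
    w <- slowWriter(src, dest, bytesPerTick = bytesPerTick,
                    cutMidRecord = cutMidRecord, seed = seed,
                    format = format)
    while (w$step() > 0L)
        if (tick > 0) Sys.sleep(tick)
    invisible(dest)
}
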