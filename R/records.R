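## Incremental, boundary-safe FASTQ/FASTA scanning from byte buffers that may
## end mid-record, plus canonical serialization. The scanners are the
## foundation of the streaming reader: they must never consume a truncated
## record while the file may still grow.

stopQC <- function(class, fmt, ...) {
    stop(structure(class = c(class, "streamqc_error", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

emptyScan <- function(format)
    list(records = SeqRecords(format = format), consumedBytes = 0L)

## Split a raw buffer into lines. Returns the line texts (CR stripped), the
## number of newline-terminated lines, and the byte offset of the end of each
## newline (1-based, i.e. bytes consumed through that line).
splitBufferLines <- function(buffer) {
    nl <- which(buffer == as.raw(10L))
    txt <- rawToChar(buffer)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    nterm <- length(nl)
    hasPartial <- length(buffer) > 0L && buffer[length(buffer)] != as.raw(10L)
    ## strsplit drops a run of trailing separators: "a\n\n" -> c("a",""),
    ## but "a\n" -> "a"; reconstruct empty terminated lines if needed.
    want <- nterm + as.integer(hasPartial)
    if (length(lines) < want)
        lines <- c(lines, rep("", want - length(lines)))
    lines <- sub("\r$", "", lines, useBytes = TRUE)
    list(lines = lines, nTerminated = nterm, hasPartial = hasPartial,
         nlEnd = nl)
}

#' Scan a FASTQ byte buffer for complete records
#'
#' Incremental FASTQ parser for streams that may end mid-record. The buffer
#' must start at a record boundary (or be empty). Records are strict
#' 4-logical-line FASTQ: header (`@...`), bases, separator (`+`, optionally
#' repeating the identifier, which is accepted and dropped), quality. A
#' record is returned only when all four of its lines are newline-terminated
#' and the quality length equals the bases length -- it is this length
#' equality, not the `@` character (which can legally open a quality
#' string), that makes streaming record-boundary detection unambiguous.
#' With `atEnd = TRUE` a well-formed final record lacking only its trailing
#' newline is also returned; any other leftover at end of input is an
#' error. Line endings `\n` and `\r\n` are both accepted.
#'
#' @param buffer raw vector (or single character string) holding a
#'   prefix-aligned slice of a FASTQ stream.
#' @param atEnd logical: is this known to be the end of the stream?
#' @return list with `records` (a [SeqRecords-class]) and `consumedBytes`,
#'   the length of the buffer prefix fully accounted for by the returned
#'   records; re-scanning exactly that prefix yields the same records, and
#'   unconsumed tail bytes must be fed back in front of the next buffer.
#' @examples
#' buf <- charToRaw("@r1\nACGT\n+\nIIII\n@r2\nGG")
#' scanFastq(buf, atEnd = FALSE)   # one record; r2's bytes not consumed
#' @seealso [scanFasta()], [writeRecords()]
#' @export
scanFastq <- function(buffer, atEnd = FALSE) {
    if (is.character(buffer)) buffer <- charToRaw(buffer)
    if (length(buffer) == 0L) return(emptyScan("fastq"))
    sp <- splitBufferLines(buffer)
    usable <- if (atEnd) sp$lines else sp$lines[seq_len(sp$nTerminated)]
    if (atEnd && sp$hasPartial && !nzchar(usable[length(usable)]))
        usable <- usable[-length(usable)]
    nrec <- length(usable) %/% 4L
    if (atEnd && length(usable) %% 4L != 0L)
        stopQC("streamqc_parse_error",
               "malformed FASTQ: %d leftover line(s) at end of input",
               length(usable) %% 4L)
    if (nrec == 0L) return(emptyScan("fastq"))
    hdr <- usable[seq.int(1L, by = 4L, length.out = nrec)]
    seqs <- usable[seq.int(2L, by = 4L, length.out = nrec)]
    plus <- usable[seq.int(3L, by = 4L, length.out = nrec)]
    qual <- usable[seq.int(4L, by = 4L, length.out = nrec)]
    bad <- !startsWith(hdr, "@")
    if (any(bad))
        stopQC("streamqc_parse_error",
               "malformed FASTQ: record %d does not start with '@' (got %s)",
               which(bad)[1L], deparse(substr(hdr[which(bad)[1L]], 1L, 20L)))
    bad <- !startsWith(plus, "+")
    if (any(bad))
        stopQC("streamqc_parse_error",
               "malformed FASTQ: record %d separator line does not start with '+'",
               which(bad)[1L])
    bad <- nchar(qual, type = "bytes") != nchar(seqs, type = "bytes")
    if (any(bad))
        stopQC("streamqc_parse_error",
               "malformed FASTQ: record %d quality length (%d) != bases length (%d)",
               which(bad)[1L],
               nchar(qual[which(bad)[1L]], type = "bytes"),
               nchar(seqs[which(bad)[1L]], type = "bytes"))
    consumed <- if (atEnd) length(buffer) else sp$nlEnd[4L * nrec]
    list(records = SeqRecords(substring(hdr, 2L), seqs, qual,
                              format = "fastq"),
         consumedBytes = as.integer(consumed))
}

#' Scan a FASTA byte buffer for complete records
#'
#' Incremental FASTA parser. Sequences may span multiple lines; a record is
#' complete only once the next `>` header has been seen, or at end of input
#' (`atEnd = TRUE`), because a growing stream can always append further
#' sequence lines to the last record. When `atEnd = FALSE`,
#' `consumedBytes` therefore stops just before the last header seen.
#'
#' @inheritParams scanFastq
#' @return As [scanFastq()], with FASTA records (multi-line sequences
#'   concatenated).
#' @examples
#' scanFasta(">a\nACGT\n>b\nGG", atEnd = FALSE)  # only record a
#' scanFasta(">a\nACGT\n>b\nGG", atEnd = TRUE)   # records a and b
#' @export
scanFasta <- function(buffer, atEnd = FALSE) {
    if (is.character(buffer)) buffer <- charToRaw(buffer)
    if (length(buffer) == 0L) return(emptyScan("fasta"))
    sp <- splitBufferLines(buffer)
    usable <- if (atEnd) sp$lines else sp$lines[seq_len(sp$nTerminated)]
    if (length(usable) == 0L) return(emptyScan("fasta"))
    if (!startsWith(usable[1L], ">"))
        stopQC("streamqc_parse_error",
               "malformed FASTA: buffer does not start with '>' (got %s)",
               deparse(substr(usable[1L], 1L, 20L)))
    hdrIdx <- which(startsWith(usable, ">"))
    nhdr <- length(hdrIdx)
    emit <- if (atEnd) nhdr else nhdr - 1L
    if (emit <= 0L) return(emptyScan("fasta"))
    ends <- c(hdrIdx[-1L] - 1L, length(usable))
    ids <- substring(usable[hdrIdx[seq_len(emit)]], 2L)
    if (any(!nzchar(trimws(ids))))
        stopQC("streamqc_parse_error",
               "malformed FASTA: header with empty identifier (record %d)",
               which(!nzchar(trimws(ids)))[1L])
    bases <- vapply(seq_len(emit), function(i) {
        from <- hdrIdx[i] + 1L; to <- ends[i]
        if (from > to) "" else paste0(usable[from:to], collapse = "")
    }, character(1L))
    consumed <- if (atEnd) length(buffer) else sp$nlEnd[hdrIdx[nhdr] - 1L]
    list(records = SeqRecords(ids, bases, format = "fasta"),
         consumedBytes = as.integer(consumed))
}

#' Scan a buffer in either format
#'
#' @inheritParams scanFastq
#' @param format `"fastq"` or `"fasta"`.
#' @return As [scanFastq()].
#' @export
scanRecords <- function(buffer, format, atEnd = FALSE) {
    switch(match.arg(format, c("fastq", "fasta")),
           fastq = scanFastq(buffer, atEnd),
           fasta = scanFasta(buffer, atEnd))
}

#' Canonical serialization of records
#'
#' FASTQ records serialize as `@id\nbases\n+\nquality\n` (the separator
#' line's optional repeated identifier is never emitted); FASTA records as
#' `>id\nbases\n` with a single sequence line. Scanning the result with
#' `atEnd = TRUE` round-trips the records (multi-line FASTA input is
#' normalized to one sequence line).
#'
#' @param records a [SeqRecords-class] object.
#' @return A raw vector of serialized bytes.
#' @examples
#' rawToChar(writeRecords(SeqRecords("r1", "ACGT", "IIII")))
#' @export
writeRecords <- function(records) {
    stopifnot(is(records, "SeqRecords"))
    if (length(records) == 0L) return(raw(0L))
    txt <- if (records@format == "fastq")
        paste0("@", records@id, "\n", records@bases, "\n+\n",
               records@quality, "\n", collapse = "")
    else
        paste0(">", records@id, "\n", records@bases, "\n", collapse = "")
    charToRaw(txt)
}

#' Write records to a file
#'
#' @param records a [SeqRecords-class] object.
#' @param path destination file.
#' @param append append to an existing file instead of truncating.
#' @return `path`, invisibly.
#' @export
writeSeqFile <- function(records, path, append = FALSE) {
    con <- file(path, if (append) "ab" else "wb")
    on.exit(close(con))
    writeBin(writeRecords(records), con)
    invisible(path)
}

readAllBytes <- function(path) {
    ## transparently handles gzip (complete files only)
    con <- gzfile(path, "rb")
    on.exit(close(con))
    out <- list()
    repeat {
        b <- readBin(con, "raw", n = 1048576L)
        if (length(b) == 0L) break
        out[[length(out) + 1L]] <- b
    }
    do.call(c, c(out, list(raw(0L))))
}

#' Detect sequence format from the first non-whitespace byte
#'
#' `@` means FASTQ, `>` means FASTA (gzip is handled transparently).
#'
#' @param path file to inspect.
#' @return `"fastq"` or `"fasta"`.
#' @export
detectFormat <- function(path) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    b <- readBin(con, "raw", n = 4096L)
    b <- b[!b %in% as.raw(c(9L, 10L, 13L, 32L))]
    if (length(b) == 0L)
        stopQC("streamqc_parse_error",
               "cannot detect format of empty file '%s'", path)
    switch(rawToChar(b[1L]),
           "@" = "fastq", ">" = "fasta",
           stopQC("streamqc_parse_error",
                  "cannot detect format of '%s': first byte %s is neither '@' nor '>'",
                  path, deparse(rawToChar(b[1L]))))
}

#' Read a complete FASTQ/FASTA file
#'
#' Batch (whole-file) read; plain or gzip-compressed input. Growing files
#' should instead be followed with [newStreamSource()]/[pollSource()].
#'
#' @param path input file.
#' @param format `"auto"` (default, detect from the first byte), `"fastq"`
#'   or `"fasta"`.
#' @return A [SeqRecords-class] object.
#' @export
readSeqFile <- function(path, format = "auto") {
    if (!file.exists(path))
        stopQC("streamqc_io_error", "no such file: '%s'", path)
    buf <- readAllBytes(path)
    if (length(buf) == 0L) {
        fmt <- if (format == "auto") "fastq" else format
        return(SeqRecords(format = fmt))
    }
    if (format == "auto") format <- detectFormat(path)
    scanRecords(buf, format, atEnd = TRUE)$records
}
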