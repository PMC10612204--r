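#' @import methods
NULL

## central value classes ------------------------------------------------------

#' SeqRecords: a vector of sequencing reads
#'
#' An S4 container holding zero or more reads of a single format. A FASTQ
#' record carries a Phred+33 quality string of the same length as its bases;
#' a FASTA record carries no quality. All quality-aware operations in the
#' package interpret quality characters as `utf8ToInt(ch) - 33`.
#'
#' @slot id character vector of identifiers (header line without the leading
#'   `@`/`>` marker; may include a description after whitespace).
#' @slot bases character vector of base strings. The alphabet is not
#'   constrained at parse time: non-IUPAC letters are a matter for the
#'   `noniupac` pipeline filter, not for the parser.
#' @slot quality character vector of Phred+33 quality strings (`NA` for every
#'   element when `format == "fasta"`).
#' @slot format single string, `"fastq"` or `"fasta"`.
#'
#' @seealso [SeqRecords()], [scanFastq()], [scanFasta()], [writeRecords()]
#' @name SeqRecords-class
#' @aliases SeqRecords-class
#' @exportClass SeqRecords
setClass("SeqRecords",
    representation(id = "character", bases = "character",
                   quality = "character", format = "character"),
    prototype(id = character(), bases = character(),
              quality = character(), format = "fastq"))

setValidity("SeqRecords", function(object) {
    msg <- character()
    if (length(object@format) != 1L ||
        !object@format %in% c("fastq", "fasta"))
        msg <- c(msg, "'format' must be \"fastq\" or \"fasta\"")
    n <- length(object@id)
    if (length(object@bases) != n || length(object@quality) != n)
        msg <- c(msg, "id, bases and quality must have equal length")
    if (any(grepl("[\r\n]", object@id)))
        msg <- c(msg, "identifiers must not contain line breaks")
    if (length(msg) == 0L && n > 0L) {
        if (object@format == "fastq") {
            if (anyNA(object@quality))
                msg <- c(msg, "FASTQ records require a quality string")
            else if (any(nchar(object@quality, type = "bytes") !=
                         nchar(object@bases, type = "bytes")))
                msg <- c(msg, "quality length must equal bases length")
        } else {
            if (!all(is.na(object@quality)))
                msg <- c(msg, "FASTA records must not carry quality strings")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SeqRecords object
#'
#' @param id character vector of identifiers.
#' @param bases character vector of base strings, same length as `id`.
#' @param quality character vector of Phred+33 quality strings for FASTQ, or
#'   `NULL` for FASTA.
#' @param format `"fastq"` or `"fasta"`; defaults to `"fastq"` when quality
#'   is supplied, `"fasta"` otherwise.
#' @return A [SeqRecords-class] object.
#' @examples
#' SeqRecords("r1", "ACGT", "IIII")
#' SeqRecords(c("a", "b"), c("ACGT", "GG"), format = "fasta")
#' @export
SeqRecords <- function(id = character(), bases = character(),
                       quality = NULL, format = NULL) {
    if (is.null(format))
        format <- if (is.null(quality)) "fasta" else "fastq"
    if (is.null(quality))
        quality <- rep(NA_character_, length(id))
    new("SeqRecords", id = as.character(id), bases = as.character(bases),
        quality = as.character(quality), format = format)
}

#' @describeIn SeqRecords number of records.
#' @param x a `SeqRecords` object.
#' @export
setMethod("length", "SeqRecords", function(x) length(x@id))

#' @export
setMethod("[", "SeqRecords", function(x, i, j, ..., drop = TRUE) {
    initialize(x, id = x@id[i], bases = x@bases[i], quality = x@quality[i])
})

#' @export
setMethod("c", "SeqRecords", function(x, ...) {
    rest <- list(...)
    for (y in rest) {
        stopifnot(is(y, "SeqRecords"))
        if (length(y) == 0L) next
        if (length(x) > 0L && y@format != x@format)
            stop("cannot concatenate SeqRecords of different formats")
        fmt <- if (length(x) == 0L) y@format else x@format
        x <- new("SeqRecords", id = c(x@id, y@id),
                 bases = c(x@bases, y@bases),
                 quality = c(x@quality, y@quality), format = fmt)
    }
    x
})

setMethod("show", "SeqRecords", function(object) {
    cat(sprintf("SeqRecords of %d %s record(s)\n", length(object),
                toupper(object@format)))
    n <- min(length(object), 5L)
    if (n > 0L) {
        b <- object@bases[seq_len(n)]
        long <- nchar(b) > 40L
        b[long] <- paste0(substr(b[long], 1L, 37L), "...")
        cat(sprintf("  %s  %s\n", format(object@id[seq_len(n)]), b), sep = "")
        if (length(object) > n)
            cat(sprintf("  ... and %d more\n", length(object) - n))
    }
    invisible(object)
})

## accessors -------------------------------------------------------------

#' @rdname SeqRecords-accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname SeqRecords-accessors
#' @export
setGeneric("seqBases", function(x) standardGeneric("seqBases"))
#' @rdname SeqRecords-accessors
#' @export
setGeneric("seqQuality", function(x) standardGeneric("seqQuality"))
#' @rdname SeqRecords-accessors
#' @export
setGeneric("seqFormat", function(x) standardGeneric("seqFormat"))

#' Accessors for SeqRecords
#'
#' @param x a [SeqRecords-class] object.
#' @return `seqId`, `seqBases`, `seqQuality` return character vectors;
#'   `seqFormat` returns `"fastq"` or `"fasta"`.
#' @name SeqRecords-accessors
#' @aliases seqId seqBases seqQuality seqFormat
NULL

#' @rdname SeqRecords-accessors
setMethod("seqId", "SeqRecords", function(x) x@id)
#' @rdname SeqRecords-accessors
setMethod("seqBases", "SeqRecords", function(x) x@bases)
#' @rdname SeqRecords-accessors
setMethod("seqQuality", "SeqRecords", function(x) x@quality)
#' @rdname SeqRecords-accessors
setMethod("seqFormat", "SeqRecords", function(x) x@format)

## chunks ----------------------------------------------------------------

#' Chunk: one stamped micro-batch of records
#'
#' A `Chunk` is the in-process analogue of a streaming "subfile": an ordered
#' batch of complete records (or record pairs) carrying the two-integer
#' stamp (iteration, worker) that defines global output order. Chunks with
#' stamps compared iteration-major reproduce the source record order when
#' concatenated.
#'
#' @slot iteration integer >= 1, the reading-stage iteration that produced
#'   the chunk.
#' @slot worker integer >= 1, the reader index within the iteration
#'   (worker 1 holds the earliest records).
#' @slot first [SeqRecords-class]: the records (mate 1 in paired mode).
#' @slot second [SeqRecords-class]: mate 2 records in paired mode (same
#'   length as `first`); empty otherwise.
#' @slot paired logical scalar.
#' @name Chunk-class
#' @aliases Chunk-class
#' @exportClass Chunk
setClass("Chunk",
    representation(iteration = "integer", worker = "integer",
                   first = "SeqRecords", second = "SeqRecords",
                   paired = "logical"))

setValidity("Chunk", function(object) {
    msg <- character()
    if (length(object@iteration) != 1L || object@iteration < 1L)
        msg <- c(msg, "'iteration' must be a single integer >= 1")
    if (length(object@worker) != 1L || object@worker < 1L)
        msg <- c(msg, "'worker' must be a single integer >= 1")
    if (isTRUE(object@paired)) {
        if (length(object@first) != length(object@second))
            msg <- c(msg, "paired chunk mates must have equal length")
        if (length(object@first) > 0L &&
            object@first@format != object@second@format)
            msg <- c(msg, "paired chunk mates must share a format")
    } else if (length(object@second) != 0L) {
        msg <- c(msg, "unpaired chunk must have empty 'second'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Chunk
#'
#' @param iteration,worker the stamp components (integers >= 1).
#' @param first records (mate 1 in paired mode).
#' @param second mate 2 records, or `NULL` for single-end.
#' @return A [Chunk-class].
#' @export
Chunk <- function(iteration, worker, first, second = NULL) {
    paired <- !is.null(second)
    if (is.null(second))
        second <- SeqRecords(format = first@format)
    new("Chunk", iteration = as.integer(iteration),
        worker = as.integer(worker), first = first, second = second,
        paired = paired)
}

#' @rdname stampLabel
#' @export
setGeneric("stampLabel", function(x, ...) standardGeneric("stampLabel"))

#' Render a chunk stamp as "<iteration>-<worker>"
#'
#' The label of the two-integer custom timestamp, e.g. the chunk produced by
#' worker 5 in iteration 3 is labelled `"3-5"`.
#'
#' @param x a [Chunk-class] object.
#' @param ... unused.
#' @return A single string.
#' @export
setMethod("stampLabel", "Chunk", function(x, ...)
    sprintf("%d-%d", x@iteration, x@worker))

setMethod("show", "Chunk", function(object) {
    cat(sprintf("Chunk stamp %s: %d %s%s record(s)\n", stampLabel(object),
                length(object@first), toupper(object@first@format),
                if (object@paired) " pair" else ""))
    invisible(object)
})

#' Number of payload records in a chunk (pairs count as 2)
#' @param chunk a [Chunk-class].
#' @return integer record count.
#' @export
chunkRecordCount <- function(chunk)
    length(chunk@first) * (1L + as.integer(chunk@paired))

## stream source state ---------------------------------------------------

#' StreamSource: follower state for one or two growing sequence files
#'
#' Value object tracking the incremental-read state of a single-end file or
#' a pair of mate files: committed byte offsets, carry-over bytes of a
#' trailing incomplete record, parsed-but-unpaired surplus records (paired
#' mode), and the reading-stage iteration counter. [pollSource()] consumes
#' and returns updated copies.
#'
#' @slot paths one or two file paths.
#' @slot format `"fastq"` or `"fasta"`.
#' @slot paired logical scalar.
#' @slot committed numeric, bytes fully consumed per file.
#' @slot carry list of raw vectors, unconsumed tail bytes per file (always a
#'   prefix of a record).
#' @slot pending list of [SeqRecords-class]: complete records awaiting their
#'   mate (paired mode only).
#' @slot iteration next iteration index (>= 1).
#' @slot finished logical, set once the end-of-input condition has been met
#'   and every byte consumed; monotone.
#' @slot capBytes per-iteration cap on newly read bytes per file.
#' @slot minBytesPerWorker,maxWorkers dynamic reader-count heuristic, see
#'   [chooseWorkers()].
#' @name StreamSource-class
#' @aliases StreamSource-class
#' @exportClass StreamSource
setClass("StreamSource",
    representation(paths = "character", format = "character",
                   paired = "logical", committed = "numeric",
                   carry = "list", pending = "list",
                   iteration = "integer", finished = "logical",
                   capBytes = "numeric", minBytesPerWorker = "numeric",
                   maxWorkers = "integer"))

setValidity("StreamSource", function(object) {
    msg <- character()
    np <- length(object@paths)
    if (!np %in% 1:2)
        msg <- c(msg, "'paths' must name one or two files")
    if (object@paired != (np == 2L))
        msg <- c(msg, "'paired' must match the number of paths")
    if (length(object@committed) != np || any(object@committed < 0))
        msg <- c(msg, "'committed' must be non-negative, one per file")
    if (length(object@carry) != np)
        msg <- c(msg, "'carry' must hold one raw vector per file")
    if (object@capBytes <= 0)
        msg <- c(msg, "'capBytes' must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StreamSource", function(object) {
    cat(sprintf("StreamSource (%s, %s)\n", toupper(object@format),
                if (object@paired) "paired-end" else "single-end"))
    for (k in seq_along(object@paths))
        cat(sprintf("  file %d: %s [%.0f bytes committed, %d carried]\n", k,
                    object@paths[k], object@committed[k],
                    length(object@carry[[k]])))
    cat(sprintf("  next iteration: %d; finished: %s\n", object@iteration,
                object@finished))
    invisible(object)
})

## run statistics --------------------------------------------------------

#' RunStats: bookkeeping for a streaming or batch run
#'
#' Conservation invariant: `recordsRead == recordsWritten +
#' recordsDiscarded` (pairs count as two records).
#'
#' @slot recordsRead,recordsWritten,recordsDiscarded record counts.
#' @slot iterations number of reading-stage iterations that produced data.
#' @slot chunks number of chunks (= part files) emitted.
#' @slot opDiscards named numeric: records discarded per filter operation.
#' @name RunStats-class
#' @aliases RunStats-class
#' @exportClass RunStats
setClass("RunStats",
    representation(recordsRead = "numeric", recordsWritten = "numeric",
                   recordsDiscarded = "numeric", iterations = "numeric",
                   chunks = "numeric", opDiscards = "numeric"),
    prototype(recordsRead = 0, recordsWritten = 0, recordsDiscarded = 0,
              iterations = 0, chunks = 0,
              opDiscards = structure(numeric(0), names = character(0))))

setValidity("RunStats", function(object) {
    if (!isTRUE(all.equal(object@recordsRead,
                          object@recordsWritten + object@recordsDiscarded)))
        "recordsRead must equal recordsWritten + recordsDiscarded"
    else TRUE
})

setMethod("show", "RunStats", function(object) {
    cat("Streaming QC run statistics\n")
    cat(sprintf("  records read:      %.0f\n", object@recordsRead))
    cat(sprintf("  records written:   %.0f\n", object@recordsWritten))
    cat(sprintf("  records discarded: %.0f\n", object@recordsDiscarded))
    cat(sprintf("  iterations: %.0f; chunks: %.0f\n", object@iterations,
                object@chunks))
    if (length(object@opDiscards)) {
        cat("  discarded per operation:\n")
        for (nm in names(object@opDiscards))
            cat(sprintf("    %s: %.0f\n", nm, object@opDiscards[[nm]]))
    }
    invisible(object)
})

## pipeline specification ------------------------------------------------

#' PipelineSpec: an ordered chain of QC operation specifications
#'
#' Operations are applied strictly in user order: a trimmer changes what a
#' downstream filter sees.
#'
#' @slot ops list of `list(name = <op name>, params = <named list>)`.
#' @name PipelineSpec-class
#' @aliases PipelineSpec-class
#' @exportClass PipelineSpec
setClass("PipelineSpec", representation(ops = "list"),
         prototype(ops = list()))

setMethod("show", "PipelineSpec", function(object) {
    cat(sprintf("PipelineSpec with %d operation(s)\n", length(object@ops)))
    for (op in object@ops) {
        p <- if (length(op$params))
            paste(names(op$params), vapply(op$params, format, ""),
                  sep = "=", collapse = ", ")
        else ""
        cat(sprintf("  %s%s\n", op$name, if (nzchar(p)) paste0(": ", p) else ""))
    }
    invisible(object)
})
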