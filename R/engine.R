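## Micro-batch executor: pull stamped chunks from the stream source, apply
## the pipeline, write append-only part files, track statistics, finalize on
## the end-of-input signal. The central contract: merged streaming output is
## byte-identical to batch processing of the finished input, for every
## growth schedule, cap, worker count and chunk completion order.

makeRunStats <- function(read = 0, written = 0, iterations = 0, chunks = 0,
                         opDiscards = structure(numeric(0),
                                                names = character(0))) {
    new("RunStats", recordsRead = read, recordsWritten = written,
        recordsDiscarded = read - written, iterations = iterations,
        chunks = chunks, opDiscards = opDiscards)
}

#' @rdname RunStats-class
#' @param object,x a `RunStats` object.
#' @export
setGeneric("runStatsAsList", function(x) standardGeneric("runStatsAsList"))

#' @rdname RunStats-class
#' @export
setMethod("runStatsAsList", "RunStats", function(x)
    list(records_read = x@recordsRead, records_written = x@recordsWritten,
         records_discarded = x@recordsDiscarded, iterations = x@iterations,
         chunks = x@chunks, op_discards = as.list(x@opDiscards)))

#' Apply a pipeline to one chunk
#'
#' Applies the compiled pipeline to every record (pair) of the chunk in
#' order, preserving intra-chunk order, and returns the surviving payload
#' under the same stamp. `index` is the cumulative survivor count (in stamp
#' order, at the rename point) of all earlier chunks; it makes identifier
#' renaming reproducible and independent of scheduling.
#'
#' @param chunk a [Chunk-class].
#' @param plan a plan from [buildPipeline()].
#' @param index 0-based global offset for index-using operations.
#' @return list with `chunk` (processed), `nextIndex`, `discards`,
#'   `nIn`, `nOut` (record counts, pairs counting as 2).
#' @export
processChunk <- function(chunk, plan, index = 0) {
    stopifnot(is(chunk, "Chunk"))
    res <- if (chunk@paired)
        applyPipeline(plan, chunk@first, chunk@second, index = index)
    else applyPipeline(plan, chunk@first, index = index)
    out <- Chunk(chunk@iteration, chunk@worker, res$records,
                 if (chunk@paired) res$second)
    list(chunk = out, nextIndex = res$nextIndex, discards = res$discards,
         nIn = chunkRecordCount(chunk), nOut = chunkRecordCount(out))
}

## flatten a paired chunk into an interleaved single-end chunk
## (used by the 'independent' pair policy)
flattenChunk <- function(chunk) {
    if (!chunk@paired) return(chunk)
    Chunk(chunk@iteration, chunk@worker,
          zipRecords(chunk@first, chunk@second))
}

addCounts <- function(a, b) {
    for (nm in names(b)) a[nm] <- (if (is.na(a[nm])) 0 else a[nm]) + b[nm]
    a
}

#' Run the streaming quality-control pipeline
#'
#' Follows one or two (paired) FASTQ/FASTA files on disk -- possibly still
#' being written by a downloader -- and processes complete records as they
#' appear: each polling iteration extracts newly completed records under a
#' per-iteration byte cap, splits them into stamped chunks, applies the
#' pipeline per chunk and appends exactly one part file per chunk under its
#' stamp partition (append semantics: parts already written never change).
#' On the end-of-input signal the run is finalized with a `_DONE` marker
#' and, optionally, merged into ordinary FASTQ/FASTA file(s) whose content
#' is identical to a batch run ([runBatch()]) over the finished input.
#'
#' End of input is declared when (a) the input is registered complete
#' (`follow = FALSE`, the default), (b) `expectBytes` is reached, or (c) no
#' file growth is seen for `idleTimeout` seconds (`follow = TRUE` without
#' `expectBytes`).
#'
#' @param input input file (mate 1 for paired mode); plain FASTQ/FASTA, or
#'   gzip when `follow = FALSE`.
#' @param input2 optional mate 2 file.
#' @param ops pipeline string (see [parsePipeline()]) or
#'   [PipelineSpec-class]; `""` is the identity pipeline.
#' @param outputDir run output root (created; must not already contain a
#'   run unless `overwrite = TRUE`).
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @param pairPolicy see [buildPipeline()]; `"independent"` implies
#'   interleaved output.
#' @param capBytes per-iteration cap on newly read bytes per file.
#' @param minBytesPerWorker,maxWorkers dynamic chunking heuristic, see
#'   [chooseWorkers()].
#' @param pollInterval seconds to sleep between idle polls in follow mode.
#' @param follow follow a growing file (`TRUE`) or treat the input as
#'   complete (`FALSE`).
#' @param idleTimeout follow-mode termination: seconds without growth.
#' @param expectBytes follow-mode termination: expected final byte size(s),
#'   recycled over the input files.
#' @param mergeTo,mergeTo2 if given, merge the partitioned output into
#'   these file(s) after finalization (see [mergeRun()]).
#' @param interleaved paired mode: merge into a single interleaved file.
#' @param spoolDir if given, additionally spool every raw chunk as a
#'   subfile there (see [spoolChunk()]).
#' @param tickHook optional `function()` called at the top of every loop
#'   iteration, returning `FALSE` once no more input will be produced.
#'   Lets a test (or an in-process downloader) drive file growth
#'   deterministically; when it reports exhaustion, end of input is
#'   declared without waiting for `idleTimeout`.
#' @param chunkWriteOrder `"stamp"` writes part files in stamp order;
#'   `"shuffled"` writes them in a seeded random order within each
#'   iteration, demonstrating that output order depends only on stamps.
#' @param shuffleSeed seed for `"shuffled"` write order.
#' @param parallelDispatch process the chunks of an iteration in parallel
#'   forked workers (`parallel::mclapply`); automatically disabled when the
#'   chain contains an index-using operation (rename), which is threaded
#'   sequentially in stamp order.
#' @param overwrite allow reuse of a non-empty `outputDir`.
#' @param quiet suppress per-iteration log lines (stderr).
#' @return A [RunStats-class] object.
#' @seealso [runBatch()], [mergeRun()], [newStreamSource()]
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeSeqFile(SeqRecords(c("a", "b"), c("ACGTT", "GGGGA"),
#'                         c("IIIII", "##III")), fq)
#' out <- tempfile()
#' runStream(fq, ops = "quality:min=25", outputDir = out,
#'           mergeTo = file.path(out, "kept.fastq"))
#' @export
runStream <- function(input, input2 = NULL, ops = "", outputDir,
                      format = "auto",
                      pairPolicy = c("discard-pair", "independent"),
                      capBytes = 64 * 1024^2,
                      minBytesPerWorker = 4 * 1024^2,
                      maxWorkers = parallel::detectCores(),
                      pollInterval = 1, follow = FALSE, idleTimeout = 10,
                      expectBytes = NULL, mergeTo = NULL, mergeTo2 = NULL,
                      interleaved = FALSE, spoolDir = NULL, tickHook = NULL,
                      chunkWriteOrder = c("stamp", "shuffled"),
                      shuffleSeed = NULL, parallelDispatch = FALSE,
                      overwrite = FALSE, quiet = TRUE) {
    pairPolicy <- match.arg(pairPolicy)
    chunkWriteOrder <- match.arg(chunkWriteOrder)
    paired <- !is.null(input2)
    if (pairPolicy == "independent" && paired) interleaved <- TRUE
    if (dir.exists(outputDir) &&
        length(list.files(outputDir)) > 0L && !overwrite)
        stopQC("streamqc_io_error",
               "output directory '%s' is not empty (use overwrite = TRUE)",
               outputDir)
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)

    tickAlive <- if (is.null(tickHook)) NA else !isFALSE(tickHook())
    if (format == "auto") {
        ## in follow mode the file may not hold its first byte yet
        repeat {
            fmt <- tryCatch(detectFormat(input),
                            streamqc_parse_error = function(e) NULL)
            if (!is.null(fmt) || !follow || isFALSE(tickAlive)) break
            if (!is.null(tickHook)) {
                if (isFALSE(tickHook())) tickAlive <- FALSE
            } else Sys.sleep(pollInterval)
        }
        format <- if (is.null(fmt)) detectFormat(input) else fmt
    }
    plan <- buildPipeline(ops, inputFormat = format, pairPolicy = pairPolicy)
    state <- newStreamSource(input, input2, format = format,
                             capBytes = capBytes,
                             minBytesPerWorker = minBytesPerWorker,
                             maxWorkers = maxWorkers)
    shuffleRng <- if (chunkWriteOrder == "shuffled") {
        seed <- if (is.null(shuffleSeed)) 0L else shuffleSeed
        local({
            rng <- new.env()
            withr::with_seed(seed, rng$state <- .Random.seed)
            rng
        })
    }

    nRead <- 0; nWritten <- 0; nChunks <- 0L
    opDiscards <- structure(numeric(0), names = character(0))
    renameIndex <- 0
    emittedIter <- integer(0); emittedWorker <- integer(0)
    lastSizes <- sum(file.size(state@paths))
    lastGrowth <- Sys.time()

    endDeclared <- function() {
        if (!follow) return(TRUE)
        if (!is.na(tickAlive) && isFALSE(tickAlive)) return(TRUE)
        sizes <- sum(file.size(state@paths))
        if (sizes > lastSizes) {
            lastSizes <<- sizes; lastGrowth <<- Sys.time()
        }
        if (!is.null(expectBytes))
            return(all(file.size(state@paths) >=
                       rep(expectBytes, length.out = length(state@paths))))
        as.numeric(difftime(Sys.time(), lastGrowth, units = "secs")) >=
            idleTimeout
    }

    repeat {
        if (!is.null(tickHook) && !isFALSE(tickAlive))
            if (isFALSE(tickHook())) tickAlive <- FALSE
        atEnd <- endDeclared()
        res <- pollSource(state, atEnd = atEnd)
        state <- res$state
        chunks <- res$chunks
        if (pairPolicy == "independent")
            chunks <- lapply(chunks, flattenChunk)
        if (length(chunks) > 0L) {
            if (!is.null(spoolDir))
                for (ch in chunks) spoolChunk(ch, spoolDir)
            processed <- if (parallelDispatch && !plan$hasRename &&
                             length(chunks) > 1L)
                parallel::mclapply(chunks, processChunk, plan = plan,
                                   mc.cores = min(length(chunks),
                                                  state@maxWorkers))
            else {
                out <- vector("list", length(chunks))
                for (j in seq_along(chunks)) {   # stamp order
                    out[[j]] <- processChunk(chunks[[j]], plan,
                                             index = renameIndex)
                    renameIndex <- out[[j]]$nextIndex
                }
                out
            }
            writeOrder <- seq_along(processed)
            if (!is.null(shuffleRng) && length(processed) > 1L) {
                old <- .GlobalEnv$.Random.seed
                assign(".Random.seed", shuffleRng$state, envir = .GlobalEnv)
                writeOrder <- sample(writeOrder)
                shuffleRng$state <- .GlobalEnv$.Random.seed
                if (!is.null(old))
                    assign(".Random.seed", old, envir = .GlobalEnv)
            }
            for (j in writeOrder) {
                pc <- processed[[j]]
                writeChunkPart(pc$chunk, outputDir)
                nRead <- nRead + pc$nIn
                nWritten <- nWritten + pc$nOut
                nChunks <- nChunks + 1L
                opDiscards <- addCounts(opDiscards, pc$discards)
                emittedIter <- c(emittedIter, pc$chunk@iteration)
                emittedWorker <- c(emittedWorker, pc$chunk@worker)
                if (!quiet)
                    message(sprintf("[streamqc] stamp %s: %d in, %d out",
                                    stampLabel(pc$chunk), pc$nIn, pc$nOut))
            }
        }
        if (state@finished) break
        if (length(chunks) == 0L && !atEnd && follow &&
            is.null(tickHook) && !isFALSE(tickAlive))
            Sys.sleep(pollInterval)
    }

    meta <- list(paired = paired && pairPolicy == "discard-pair",
                 interleaved = interleaved,
                 format = plan$outputFormat,
                 iterations_emitted = emittedIter,
                 workers_emitted = emittedWorker,
                 records_read = nRead, records_written = nWritten)
    writeDoneMarker(outputDir, meta)
    if (!is.null(mergeTo))
        mergeRun(outputDir, mergeTo, mergeTo2, interleaved = interleaved)
    makeRunStats(read = nRead, written = nWritten,
                 iterations = if (length(emittedIter)) max(emittedIter)
                              else 0,
                 chunks = nChunks, opDiscards = opDiscards)
}

#' Run the same pipeline in one batch pass
#'
#' Reads the complete input file(s) at rest, applies the pipeline once and
#' writes ordinary FASTQ/FASTA output. This is the reference semantics that
#' streaming runs reproduce exactly: for any finished input,
#' `runStream(...)` merged output is byte-identical to `runBatch(...)`
#' output.
#'
#' @inheritParams runStream
#' @param output destination file (mate 1 for paired non-interleaved
#'   output).
#' @param output2 mate 2 destination.
#' @return A [RunStats-class] object.
#' @export
runBatch <- function(input, input2 = NULL, ops = "", output, output2 = NULL,
                     format = "auto",
                     pairPolicy = c("discard-pair", "independent"),
                     interleaved = FALSE) {
    pairPolicy <- match.arg(pairPolicy)
    paired <- !is.null(input2)
    if (pairPolicy == "independent" && paired) interleaved <- TRUE
    if (format == "auto") format <- detectFormat(input)
    plan <- buildPipeline(ops, inputFormat = format, pairPolicy = pairPolicy)
    first <- readSeqFile(input, format)
    if (paired) {
        second <- readSeqFile(input2, format)
        if (length(first) != length(second))
            stopQC("streamqc_pair_error",
                   "paired inputs have unequal record counts (%d vs %d)",
                   length(first), length(second))
        if (pairPolicy == "independent") {
            first <- zipRecords(first, second)
            second <- NULL
            paired <- FALSE
        }
    } else second <- NULL
    res <- applyPipeline(plan, first, second)
    nIn <- length(first) * (1L + as.integer(paired))
    nOut <- length(res$records) * (1L + as.integer(paired))
    if (paired && !interleaved) {
        if (is.null(output2))
            stopQC("streamqc_config_error",
                   "paired batch run: give 'output2' or interleaved = TRUE")
        writeSeqFile(res$records, output)
        writeSeqFile(res$second, output2)
    } else if (paired) {
        writeSeqFile(zipRecords(res$records, res$second), output)
    } else {
        writeSeqFile(res$records, output)
    }
    makeRunStats(read = nIn, written = nOut, iterations = 1, chunks = 1,
                 opDiscards = res$discards)
}
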