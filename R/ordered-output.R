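## Stamp-partitioned part files plus the ordered merge. Output order depends
## only on the (iteration, worker) stamps -- never on filesystem modification
## times, which give no ordering guarantee for independently processed
## chunks.

DONE_MARKER <- "_DONE"

#' Partition directory for a chunk stamp
#'
#' Part files for the chunk stamped `(iteration, worker)` live in
#' `<root>/timestamp=<iteration>-<worker>`. Both components are zero-padded
#' to a fixed width so that plain lexicographic sorting of directory names
#' equals the iteration-major total order of stamps even once indices reach
#' 10 (unpadded, `"10"` would sort before `"9"`).
#'
#' @param root output root directory.
#' @param iteration,worker stamp components (integers >= 1).
#' @param width zero-padding width (default 6).
#' @return the partition directory path(s) (vectorized over stamps).
#' @examples
#' partitionPath("out", 3, 5)   # out/timestamp=000003-000005
#' @export
partitionPath <- function(root, iteration, worker, width = 6L) {
    file.path(root, sprintf("timestamp=%0*d-%0*d", width,
                            as.integer(iteration), width,
                            as.integer(worker)))
}

## interleave mate records (pair i occupies positions 2i-1, 2i)
zipRecords <- function(first, second) {
    stopifnot(length(first) == length(second))
    ord <- as.vector(rbind(seq_along(first@id),
                           length(first) + seq_along(second@id)))
    all <- c(first, second)
    all[ord]
}

unzipRecords <- function(records) {
    n <- length(records)
    if (n %% 2L != 0L)
        stopQC("streamqc_pair_error",
               "interleaved payload has an odd record count (%d)", n)
    odd <- seq_len(n) %% 2L == 1L
    list(first = records[odd], second = records[!odd])
}

#' Write one processed chunk as an append-only part file
#'
#' Creates the chunk's stamp partition directory and writes exactly one part
#' file into it, atomically (temp file then rename): previously written
#' parts are never modified. Paired payloads are stored with mates adjacent
#' (interleaved), which makes pairing loss impossible mid-pipeline; the
#' ordered merge splits them back out. Chunks whose payload was entirely
#' filtered away still produce an (empty) part so that the partition set
#' matches the emitted stamp set exactly.
#'
#' @param chunk a (processed) [Chunk-class].
#' @param root output root directory.
#' @return the part file path, invisibly.
#' @export
writeChunkPart <- function(chunk, root) {
    dir <- partitionPath(root, chunk@iteration, chunk@worker)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (chunk@first@format == "fastq") "fastq" else "fasta"
    payload <- if (chunk@paired) zipRecords(chunk@first, chunk@second)
        else chunk@first
    part <- file.path(dir, sprintf("part-%05d.%s", 0L, ext))
    tmp <- tempfile("part-", tmpdir = root)
    con <- file(tmp, "wb")
    writeBin(writeRecords(payload), con)
    close(con)
    if (!file.rename(tmp, part))
        stopQC("streamqc_io_error", "cannot move part file into '%s'", dir)
    invisible(part)
}

writeDoneMarker <- function(root, meta) {
    jsonlite::write_json(meta, file.path(root, DONE_MARKER),
                         auto_unbox = TRUE)
    invisible(root)
}

readDoneMarker <- function(root) {
    p <- file.path(root, DONE_MARKER)
    if (!file.exists(p))
        stopQC("streamqc_io_error",
               "no %s marker under '%s': run incomplete or aborted",
               DONE_MARKER, root)
    jsonlite::read_json(p, simplifyVector = TRUE)
}

#' List partition directories of a run in stamp order
#' @param root output root directory.
#' @return character vector of partition directory paths, sorted so that
#'   their order equals the stamp total order.
#' @export
listPartitions <- function(root) {
    d <- list.files(root, pattern = "^timestamp=", full.names = TRUE)
    d[order(basename(d))]
}

#' Merge stamp-partitioned output into final file(s)
#'
#' Concatenates part-file contents in (stamp, part name) order into a single
#' output file, restoring the original input order of surviving records. A
#' paired run is split back into two synchronized mate files with equal
#' record counts (or kept as one interleaved file with
#' `interleaved = TRUE`). The merge is read-only over the partitions and
#' idempotent; it refuses to run without the `_DONE` marker written at
#' successful finalization, and verifies that every stamp the run emitted
#' has its partition present.
#'
#' @param root run output root (as passed to [runStream()]).
#' @param dest destination file (mate 1 for paired output).
#' @param dest2 mate 2 destination (paired, non-interleaved output only).
#' @param interleaved write pairs interleaved into `dest` instead of
#'   splitting into `dest`/`dest2`.
#' @return character vector of destination path(s), invisibly.
#' @export
mergeRun <- function(root, dest, dest2 = NULL, interleaved = FALSE) {
    meta <- readDoneMarker(root)
    dirs <- listPartitions(root)
    expect <- partitionPath(root, meta$iterations_emitted,
                            meta$workers_emitted)
    missing <- setdiff(basename(expect), basename(dirs))
    if (length(missing))
        stopQC("streamqc_io_error",
               "missing partition(s) for emitted stamp(s): %s",
               paste(missing, collapse = ", "))
    paired <- isTRUE(meta$paired)
    if (paired && !interleaved && is.null(dest2))
        stopQC("streamqc_config_error",
               "paired run: give 'dest2' or use interleaved = TRUE")
    splitPairs <- paired && !interleaved
    con1 <- file(dest, "wb")
    on.exit(close(con1), add = TRUE)
    if (splitPairs) {
        con2 <- file(dest2, "wb")
        on.exit(close(con2), add = TRUE)
    }
    for (d in dirs) {
        parts <- list.files(d, pattern = "^part-", full.names = TRUE)
        for (p in parts[order(basename(parts))]) {
            bytes <- readBin(p, "raw", n = file.size(p))
            if (!splitPairs) {
                writeBin(bytes, con1)
            } else if (length(bytes) > 0L) {
                recs <- scanRecords(bytes, meta$format, atEnd = TRUE)$records
                mates <- unzipRecords(recs)
                writeBin(writeRecords(mates$first), con1)
                writeBin(writeRecords(mates$second), con2)
            }
        }
    }
    invisible(c(dest, if (splitPairs) dest2))
}
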