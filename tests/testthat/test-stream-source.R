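mkFastqFile <- function(path, n, prefix = "r", len = 8, seed = 1) {
    generateReads(n, path, readLength = len, seed = seed, idPrefix = prefix)
    readSeqFile(path)
}

drainSource <- function(state, atEnd = TRUE) {
    chunks <- list()
    while (!state@finished) {
        res <- pollSource(state, atEnd = atEnd)
        state <- res$state
        chunks <- c(chunks, res$chunks)
        if (atEnd == FALSE && length(res$chunks) == 0) break
    }
    list(chunks = chunks, state = state)
}

test_that("chooseWorkers follows the clamped ceiling rule", {
    expect_equal(chooseWorkers(0), 1L)
    mbw <- 4 * 1024^2
    expect_equal(chooseWorkers(10 * mbw, maxWorkers = 4), 4L)
    expect_equal(chooseWorkers(2.5 * mbw, maxWorkers = 8), 3L)
})

test_that("records are split across workers contiguously and in order", {
    f <- withr::local_tempfile(fileext = ".fastq")
    all <- mkFastqFile(f, 10, len = 6)
    st <- newStreamSource(f, minBytesPerWorker = ceiling(file.size(f) / 2),
                          maxWorkers = 2)
    res <- pollSource(st, atEnd = TRUE)
    expect_equal(length(res$chunks), 2L)
    expect_equal(vapply(res$chunks, stampLabel, ""), c("1-1", "1-2"))
    expect_equal(seqId(res$chunks[[1]]@first), seqId(all)[1:5])
    expect_equal(seqId(res$chunks[[2]]@first), seqId(all)[6:10])
    expect_true(res$state@finished)
})

test_that("an incomplete trailing record is withheld until its bytes arrive", {
    f <- withr::local_tempfile(fileext = ".fastq")
    rec1 <- "@a\nACGT\n+\nIIII\n"
    rec2head <- "@b\nGGGG\n+\nJJ"
    writeLines(paste0(rec1, rec2head), f, sep = "")
    st <- newStreamSource(f, maxWorkers = 1)
    res <- pollSource(st, atEnd = FALSE)
    expect_equal(length(res$chunks), 1L)
    expect_equal(seqId(res$chunks[[1]]@first), "a")
    expect_equal(res$state@committed[1], nchar(rec1))
    expect_equal(length(res$state@carry[[1]]), nchar(rec2head))
    # idle poll: nothing new, state unchanged
    res2 <- pollSource(res$state, atEnd = FALSE)
    expect_equal(length(res2$chunks), 0L)
    expect_equal(res2$state@committed, res$state@committed)
    # record completes -> emitted with the next iteration index
    cat("JJ\n", file = f, append = TRUE)
    res3 <- pollSource(res2$state, atEnd = TRUE)
    expect_equal(seqId(res3$chunks[[1]]@first), "b")
    expect_equal(res3$chunks[[1]]@iteration, 2L)
    expect_true(res3$state@finished)
})

test_that("per-iteration byte cap is respected up to one record", {
    f <- withr::local_tempfile(fileext = ".fastq")
    mkFastqFile(f, 100, len = 20)
    recBytes <- file.size(f) / 100
    cap <- 500
    st <- newStreamSource(f, capBytes = cap, maxWorkers = 1)
    prev <- 0
    while (!st@finished) {
        res <- pollSource(st, atEnd = TRUE)
        newly <- res$state@committed[1] - prev
        expect_lte(newly, cap + recBytes)
        prev <- res$state@committed[1]
        st <- res$state
    }
    expect_equal(prev, file.size(f))
})

test_that("iteration counter advances only when chunks are produced", {
    f <- withr::local_tempfile(fileext = ".fastq")
    writeLines("@a\nAC\n+\nII\n", f, sep = "")
    st <- newStreamSource(f, maxWorkers = 1)
    res <- pollSource(st, atEnd = FALSE)    # record 'a' complete
    expect_equal(res$state@iteration, 2L)
    res2 <- pollSource(res$state, atEnd = FALSE)  # nothing new
    expect_equal(res2$state@iteration, 2L)
})

test_that("paired polling emits min(n1, n2) pairs and buffers the surplus", {
    f1 <- withr::local_tempfile(fileext = ".fastq")
    f2 <- withr::local_tempfile(fileext = ".fastq")
    r1 <- mkFastqFile(f1, 8, prefix = "p", seed = 2)
    full2 <- mkFastqFile(f2, 8, prefix = "p", seed = 3)
    # truncate mate 2 to its first 5 records
    writeSeqFile(full2[1:5], f2)
    st <- newStreamSource(f1, f2, maxWorkers = 1)
    res <- pollSource(st, atEnd = FALSE)
    expect_equal(length(res$chunks), 1L)
    expect_true(res$chunks[[1]]@paired)
    expect_equal(length(res$chunks[[1]]@first), 5L)
    expect_equal(seqId(res$chunks[[1]]@second), seqId(full2)[1:5])
    expect_equal(length(res$state@pending[[1]]), 3L)
    # mate 2 catches up; every pair is positionally matched
    writeSeqFile(full2[6:8], f2, append = TRUE)
    res2 <- pollSource(res$state, atEnd = TRUE)
    expect_equal(seqId(res2$chunks[[1]]@first), seqId(r1)[6:8])
    expect_equal(seqId(res2$chunks[[1]]@second), seqId(full2)[6:8])
    expect_true(res2$state@finished)
})

test_that("unequal paired record counts at end of input raise an error", {
    f1 <- withr::local_tempfile(fileext = ".fastq")
    f2 <- withr::local_tempfile(fileext = ".fastq")
    mkFastqFile(f1, 6, seed = 4)
    r2 <- mkFastqFile(f2, 6, seed = 5)
    writeSeqFile(r2[1:5], f2)               # one fewer record
    st <- newStreamSource(f1, f2, maxWorkers = 1)
    expect_error(pollSource(st, atEnd = TRUE),
                 "unpaired trailing", class = "streamqc_pair_error")
})

test_that("paired files of different formats are rejected", {
    f1 <- withr::local_tempfile(fileext = ".fastq")
    f2 <- withr::local_tempfile(fileext = ".fa")
    writeLines("@a\nAC\n+\nII\n", f1, sep = "")
    writeLines(">a\nAC\n", f2, sep = "")
    expect_error(newStreamSource(f1, f2), class = "streamqc_pair_error")
})

test_that("a shrinking source file is reported as corrupted", {
    f <- withr::local_tempfile(fileext = ".fastq")
    mkFastqFile(f, 10)
    st <- newStreamSource(f, maxWorkers = 1)
    st <- pollSource(st, atEnd = FALSE)$state
    writeLines("@a\nAC\n+\nII\n", f, sep = "")   # shrink
    expect_error(pollSource(st, atEnd = FALSE), "shrank",
                 class = "streamqc_io_error")
})

test_that("the final FASTA record is only emitted at end of input", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(">a\nACGT\n>b\nGG\n", f, sep = "")
    st <- newStreamSource(f, maxWorkers = 1)
    res <- pollSource(st, atEnd = FALSE)
    expect_equal(seqId(res$chunks[[1]]@first), "a")
    expect_false(res$state@finished)
    res2 <- pollSource(res$state, atEnd = TRUE)
    expect_equal(seqId(res2$chunks[[1]]@first), "b")
    expect_true(res2$state@finished)
})

test_that("spooled subfiles round-trip payload and stamp", {
    d <- withr::local_tempdir()
    recs <- SeqRecords(c("a", "b"), c("ACGT", "GG"), c("IIII", "JJ"))
    ch <- Chunk(3, 5, recs)
    p <- spoolChunk(ch, d)
    expect_match(basename(p), "subfile-000003-000005")
    lines <- readLines(p)
    expect_equal(sum(lines == "\x1e"), 2L)   # one separator per record
    back <- loadChunk(p)
    expect_equal(stampLabel(back), "3-5")
    expect_equal(recordsAsDf(back@first), recordsAsDf(recs))
    # paired: both mates inside one subfile, separator per pair
    chp <- Chunk(2, 1, recs, SeqRecords(c("a2", "b2"), c("TT", "CC"),
                                        c("KK", "LL")))
    pp <- spoolChunk(chp, d)
    expect_equal(sum(readLines(pp) == "\x1e"), 2L)
    backp <- loadChunk(pp)
    expect_true(backp@paired)
    expect_equal(seqId(backp@second), c("a2", "b2"))
})
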