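fqRec <- function(bases, quality = strrep("I", nchar(bases)), id = "r")
    SeqRecords(id, bases, quality)

test_that("mean-quality filter uses Phred+33 with inclusive bounds", {
    expect_true(filterQuality(fqRec("ACGT", "IIII"), min = 25))   # score 40
    expect_false(filterQuality(fqRec("ACGT", "!!!!"), min = 25))  # score 0
    # mean exactly at the bound is kept (':' encodes 25)
    expect_true(filterQuality(fqRec("ACGT", "::::"), min = 25))
    expect_true(filterQuality(fqRec("ACGT", "::::"), max = 25))
    expect_equal(meanQuality(fqRec("AC", "!I")), 20)
    expect_error(filterQuality(fqRec("AC", "II")), "min")
    expect_error(
        filterQuality(SeqRecords("r", "AC", format = "fasta"), min = 10),
        class = "streamqc_config_error")
})

test_that("non-IUPAC filter keeps exactly {A,T,G,C,N}, case-insensitive", {
    expect_true(filterNonIupac(fqRec("ATGCN", "IIIII")))
    expect_true(filterNonIupac(fqRec("atgcn", "IIIII")))
    expect_false(filterNonIupac(fqRec("ATGX", "IIII")))
    expect_false(filterNonIupac(fqRec("ATGU", "IIII")))
    expect_true(filterNonIupac(fqRec("", "")))   # vacuous
})

test_that("length filter bounds are inclusive", {
    r76 <- fqRec(strrep("A", 76))
    expect_true(filterLength(r76, min = 50))
    expect_false(filterLength(fqRec(strrep("A", 10)), min = 50))
    r50 <- fqRec(strrep("A", 50))
    expect_true(filterLength(r50, min = 50, max = 50))
})

test_that("base-count filter bounds each base type independently", {
    expect_false(filterBaseCount(fqRec("GGTTTT", "IIIIII"),
                                 bases = "T", max = 3))
    expect_true(filterBaseCount(fqRec("ACGT", "IIII"), bases = "T", max = 3))
    expect_false(filterBaseCount(fqRec("ACGT", "IIII"), bases = "N",
                                 min = 1))
    # per-type: 2 G and 2 C each within [1,2]; one bound violated fails
    expect_true(filterBaseCount(fqRec("GGCC", "IIII"), bases = "GC",
                                min = 1, max = 2))
    expect_false(filterBaseCount(fqRec("GGGC", "IIII"), bases = "GC",
                                 max = 2))
})

test_that("base-percentage filter uses the combined proportion", {
    expect_false(filterBasePercent(fqRec("GCGC", "IIII"), bases = "GC",
                                   max = 50))
    expect_true(filterBasePercent(fqRec("ATAT", "IIII"), bases = "GC",
                                  max = 50))
    expect_true(filterBasePercent(fqRec("ACGT", "IIII"), bases = "GC",
                                  min = 50, max = 50))
    expect_true(filterBasePercent(fqRec("", ""), bases = "GC", max = 10))
})

test_that("pattern filter is plain substring with a polarity flag", {
    expect_true(filterPattern(fqRec("ACGTACGT", strrep("I", 8)), "GTA"))
    expect_false(filterPattern(fqRec("AAAA", "IIII"), "GTA"))
    expect_true(filterPattern(fqRec("AAAA", "IIII"), "X", contains = FALSE))
    expect_false(filterPattern(fqRec("AXA", "III"), "X", contains = FALSE))
})

test_that("fixed-count trimmers slice both ends with quality in lockstep", {
    r <- fqRec("ACGTACG", "ABCDEFG")
    expect_equal(seqBases(trimLeft(r, 3)), "TACG")
    expect_equal(seqQuality(trimLeft(r, 3)), "DEFG")
    expect_equal(seqBases(trimRight(r, 3)), "ACGT")
    expect_equal(seqQuality(trimRight(r, 3)), "ABCD")
    expect_equal(seqBases(trimLeft(r, 0)), "ACGTACG")
    expect_equal(seqBases(trimRight(r, 99)), "")
    expect_equal(seqQuality(trimRight(r, 99)), "")
    expect_equal(seqId(trimLeft(r, 2)), "r")
})

test_that("percentage trimmers remove floor(len * pct / 100) bases", {
    r100 <- fqRec(strrep("A", 100))
    expect_equal(nchar(seqBases(trimRightPercent(r100, 10))), 90L)
    r99 <- fqRec(strrep("A", 99))
    expect_equal(nchar(seqBases(trimRightPercent(r99, 10))), 90L)
    expect_equal(seqBases(trimRightPercent(r99, 0)), strrep("A", 99))
    r10 <- fqRec("ABCDEFGHIJ", "0123456789")
    expect_equal(seqBases(trimLeftPercent(r10, 25)), "CDEFGHIJ")
    expect_equal(seqQuality(trimLeftPercent(r10, 25)), "23456789")
})

test_that("max-length trimming keeps the leading prefix", {
    r <- fqRec(strrep("AC", 80))   # 160 bases
    expect_equal(nchar(seqBases(trimToMaxLength(r, 100))), 100L)
    expect_equal(seqBases(trimToMaxLength(fqRec("ACGT", "IIII"), 100)),
                 "ACGT")
    expect_equal(seqBases(trimToMaxLength(fqRec("ACGT", "IIII"), 0)), "")
})

test_that("quality trimming removes rightmost bases until the mean holds", {
    q <- rawToChar(as.raw(33 + c(40, 40, 40, 2, 2)))
    r <- fqRec("ACGTA", q)
    got <- trimQualityRight(r, 30)
    expect_equal(nchar(seqBases(got)), oracleTrimQualLen(q, 30))
    expect_gte(oracleMeanQ(seqQuality(got)), 30)
    # already good -> unchanged; hopeless -> empty
    expect_equal(seqBases(trimQualityRight(fqRec("ACG", "III"), 30)), "ACG")
    expect_equal(seqBases(trimQualityRight(fqRec("ACG", "!!!"), 30)), "")
})

test_that("alphabet formatters swap T/U preserving case", {
    r <- fqRec("ATgt", "IIII")
    expect_equal(seqBases(dnaToRna(r)), "AUgu")
    expect_equal(seqBases(dnaToRna(fqRec("AAAA", "IIII"))), "AAAA")
    withr::with_seed(3, {
        x <- paste0(sample(c("A", "C", "G", "T", "t"), 30, TRUE),
                    collapse = "")
        rr <- fqRec(x, strrep("I", 30))
        expect_equal(seqBases(rnaToDna(dnaToRna(rr))), x)
    })
})

test_that("FASTQ to FASTA conversion drops quality and is idempotent", {
    r <- fqRec("ACGT", "IIII", id = "r1")
    fa <- fastqToFasta(r)
    expect_equal(seqFormat(fa), "fasta")
    expect_true(startsWith(rawToChar(writeRecords(fa)), ">"))
    expect_equal(recordsAsDf(fastqToFasta(fa))$bases, "ACGT")
    # a quality-dependent op downstream of the conversion is a build error
    expect_error(buildPipeline("fastqtofasta,quality:min=25", "fastq"),
                 class = "streamqc_config_error")
})

test_that("renaming assigns consecutive prefixed indices", {
    r <- SeqRecords(c("a", "b", "c"), c("A", "C", "G"), c("I", "I", "I"))
    expect_equal(seqId(renameIds(r, "seq")), c("seq1", "seq2", "seq3"))
    expect_equal(seqId(renameIds(r, "seq", start = 2))[1], "seq3")
    expect_equal(length(renameIds(r, "x")), 3L)
})

test_that("the pipeline grammar parses chains with op-local parameters", {
    ps <- parsePipeline("quality:min=25,noniupac;basecount:bases=T,max=3")
    expect_equal(vapply(ps@ops, `[[`, "", "name"),
                 c("quality", "noniupac", "basecount"))
    expect_equal(ps@ops[[3]]$params, list(bases = "T", max = 3))
    ps2 <- parsePipeline("pattern:seq=ACGT,contains=false")
    expect_identical(ps2@ops[[1]]$params$contains, FALSE)
    expect_error(buildPipeline("bogus", "fastq"), "registered operations",
                 class = "streamqc_config_error")
    expect_error(parsePipeline("min=25"), class = "streamqc_config_error")
    expect_error(buildPipeline("quality", "fastq"),
                 class = "streamqc_config_error")   # missing bound
    expect_error(buildPipeline("quality:min=25", "fasta"),
                 class = "streamqc_config_error")
})

test_that("compiled steps keep their own parameters", {
    plan <- buildPipeline("trimright:n=3,trimleft:n=1", "fastq")
    r <- fqRec("ABCDEFG", "ABCDEFG")
    out <- applyPipeline(plan, r)
    expect_equal(seqBases(out$records), "BCD")
})

test_that("an empty pipeline is the identity", {
    plan <- buildPipeline("", "fastq")
    r <- SeqRecords(c("a", "b"), c("AC", "GT"), c("II", "JJ"))
    out <- applyPipeline(plan, r)
    expect_equal(recordsAsDf(out$records), recordsAsDf(r))
    expect_equal(out$discards, structure(numeric(0),
                                         names = character(0)))
})

test_that("trim-then-count chain keeps only reads within the T budget", {
    # one read still holds 4 T after a 3-base right trim, the other <= 3
    recs <- SeqRecords(c("s1", "s2"), c("GGTTTTTTT", "ACGTACGTT"),
                       c(strrep("I", 9), strrep("I", 9)))
    plan <- buildPipeline("trimright:n=3,basecount:bases=T,max=3", "fastq")
    out <- applyPipeline(plan, recs)
    expect_equal(length(out$records), 1L)
    expect_equal(seqId(out$records), "s2")
    expect_equal(seqBases(out$records), "ACGTAC")   # survivor is trimmed
    expect_equal(unname(out$discards["basecount"]), 1)
})

test_that("pair policy discard-pair drops the pair when either mate fails", {
    plan <- buildPipeline("length:min=5", "fastq",
                          pairPolicy = "discard-pair")
    first <- SeqRecords(c("a/1", "b/1"), c("ACGTAC", "ACGTAC"),
                        c("IIIIII", "IIIIII"))
    second <- SeqRecords(c("a/2", "b/2"), c("ACGTAC", "ACG"),
                         c("IIIIII", "III"))
    out <- applyPipeline(plan, first, second)
    expect_equal(seqId(out$records), "a/1")
    expect_equal(seqId(out$second), "a/2")
    expect_equal(unname(out$discards["length"]), 2)  # pairs count as 2
})

test_that("ops preserve counts, purity and FASTQ length equality", {
    withr::with_seed(31, {
        n <- 60
        lens <- sample(0:25, n, replace = TRUE)
        bases <- vapply(lens, function(l)
            paste0(sample(c("A", "C", "G", "T", "N", "X", "a", "t"), l,
                          replace = TRUE), collapse = ""), character(1))
        qual <- vapply(lens, function(l)
            paste0(sample(strsplit("!#0:@IJ", "")[[1]], l, replace = TRUE),
                   collapse = ""), character(1))
        r <- SeqRecords(paste0("p", 1:n), bases, qual)
        mapChains <- c("trimleft:n=2", "trimrightp:pct=13", "maxlen:n=9",
                       "trimqual:min=20", "dnatorna", "rename:prefix=z")
        for (chain in mapChains) {
            out <- applyPipeline(buildPipeline(chain, "fastq"), r)
            expect_equal(length(out$records), n)
            expect_equal(nchar(seqBases(out$records)),
                         nchar(seqQuality(out$records)))
        }
        filterChains <- c("quality:min=20", "noniupac", "length:min=5",
                          "basepercent:bases=GC,max=60",
                          "pattern:seq=ACG,contains=true")
        for (chain in filterChains) {
            out <- applyPipeline(buildPipeline(chain, "fastq"), r)
            expect_lte(length(out$records), n)
            keptIds <- seqId(out$records)
            orig <- recordsAsDf(r)
            expect_equal(recordsAsDf(out$records),
                         orig[orig$id %in% keptIds, ],
                         ignore_attr = TRUE)   # filters never modify
        }
    })
})

test_that("record independence: chunked application equals whole-batch", {
    withr::with_seed(41, {
        r <- readSeqFile({
            f <- tempfile(fileext = ".fastq")
            generateReads(120, f, readLength = c(10, 40),
                          qualityMean = 26, qualitySd = 7, seed = 8)
            f
        })
        plan <- buildPipeline("trimrightp:pct=10,quality:min=25,noniupac",
                              "fastq")
        whole <- applyPipeline(plan, r)
        cuts <- c(0, sort(sample(1:119, 4)), 120)
        parts <- lapply(seq_len(length(cuts) - 1), function(j)
            applyPipeline(plan, r[seq.int(cuts[j] + 1, cuts[j + 1])]))
        got <- do.call(c, lapply(parts, `[[`, "records"))
        expect_equal(recordsAsDf(got), recordsAsDf(whole$records))
    })
})

test_that("filters commute but a trimmer and a filter need not", {
    r <- SeqRecords(paste0("c", 1:6),
                    c("ACGTTTT", "GGGG", "ACGTACGT", "TTTT", "NNAA", "AXC"),
                    vapply(c(7, 4, 8, 4, 4, 3), function(l) strrep("I", l),
                           character(1)))
    a <- "length:min=4"; b <- "noniupac"
    ab <- applyPipeline(buildPipeline(paste(a, b, sep = ","), "fastq"), r)
    ba <- applyPipeline(buildPipeline(paste(b, a, sep = ","), "fastq"), r)
    expect_equal(recordsAsDf(ab$records), recordsAsDf(ba$records))
    # witness: trimming first changes what the length filter sees
    tf <- applyPipeline(buildPipeline("trimright:n=4,length:min=4",
                                      "fastq"), r)
    ft <- applyPipeline(buildPipeline("length:min=4,trimright:n=4",
                                      "fastq"), r)
    expect_false(identical(seqId(tf$records), seqId(ft$records)))
})

test_that("a user-registered operation is picked up by the pipeline", {
    registerOp("revcomp_test", "map", make = function(p) function(r) {
        flip <- chartr("ACGT", "TGCA", seqBases(r))
        rev <- vapply(strsplit(flip, ""), function(x)
            paste0(rev(x), collapse = ""), character(1))
        initialize(r, bases = rev,
                   quality = vapply(strsplit(seqQuality(r), ""), function(x)
                       paste0(rev(x), collapse = ""), character(1)))
    })
    expect_true("revcomp_test" %in% listOps())
    out <- applyPipeline(buildPipeline("revcomp_test", "fastq"),
                         fqRec("AACG", "IIJK"))
    expect_equal(seqBases(out$records), "CGTT")
    expect_equal(seqQuality(out$records), "KJII")
})
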