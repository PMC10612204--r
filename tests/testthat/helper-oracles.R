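# Independent reference implementations used as oracles. These deliberately
# take different routes from the package code: line-by-line batch parsing
# instead of incremental byte scanning, per-character loops instead of
# vectorized regex/substring tricks.

# batch 4-line FASTQ parser over a complete text (readLines route)
oracleParseFastq <- function(text) {
    lines <- readLines(textConnection(text))
    if (length(lines) && lines[length(lines)] == "")
        lines <- lines[-length(lines)]
    stopifnot(length(lines) %% 4 == 0)
    n <- length(lines) / 4
    data.frame(
        id = sub("^@", "", lines[seq(1, by = 4, length.out = n)]),
        bases = lines[seq(2, by = 4, length.out = n)],
        quality = lines[seq(4, by = 4, length.out = n)],
        stringsAsFactors = FALSE)
}

# batch FASTA parser (readLines route, multi-line sequences)
oracleParseFasta <- function(text) {
    lines <- readLines(textConnection(text))
    hdr <- grep("^>", lines)
    ends <- c(hdr[-1] - 1, length(lines))
    data.frame(
        id = sub("^>", "", lines[hdr]),
        bases = vapply(seq_along(hdr), function(i)
            if (hdr[i] + 1 > ends[i]) "" else
                paste0(lines[(hdr[i] + 1):ends[i]], collapse = ""),
            character(1)),
        stringsAsFactors = FALSE)
}

oracleMeanQ <- function(q) {
    s <- as.integer(charToRaw(q)) - 33L
    if (length(s) == 0) 0 else sum(s) / length(s)
}

oracleCountBase <- function(seq, base) {
    chars <- strsplit(toupper(seq), "")[[1]]
    sum(chars == toupper(base))
}

# iterative right-trim to a target mean quality (the loop as stated)
oracleTrimQualLen <- function(q, target) {
    s <- as.integer(charToRaw(q)) - 33L
    while (length(s) > 0 && mean(s) < target)
        s <- s[-length(s)]
    length(s)
}

recordsAsDf <- function(r) {
    data.frame(id = seqId(r), bases = seqBases(r),
               quality = seqQuality(r), stringsAsFactors = FALSE)
}

expectSameRecords <- function(r, df) {
    expect_equal(length(r), nrow(df))
    expect_equal(seqId(r), df$id)
    expect_equal(seqBases(r), df$bases)
    if (!is.null(df$quality) && seqFormat(r) == "fastq")
        expect_equal(seqQuality(r), df$quality)
    invisible(TRUE)
}

fileBytes <- function(path) readBin(path, "raw", n = file.size(path))

expectFilesIdentical <- function(a, b)
    expect_identical(fileBytes(a), fileBytes(b))

# a small deterministic FASTQ text with awkward features: quality strings
# starting with '@' or '+', mixed lengths
makeTrickyFastq <- function(n = 20, seed = 99) {
    withr::with_seed(seed, {
        lens <- sample(5:30, n, replace = TRUE)
        ids <- paste0("t", seq_len(n))
        bases <- vapply(lens, function(l)
            paste0(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE),
                   collapse = ""), character(1))
        qual <- vapply(seq_len(n), function(i) {
            ch <- sample(strsplit("!@+ABCDIJ5:", "")[[1]], lens[i],
                         replace = TRUE)
            if (i %% 3 == 0) ch[1] <- "@"   # quality line opens with '@'
            if (i %% 5 == 0) ch[1] <- "+"
            paste0(ch, collapse = "")
        }, character(1))
        paste0("@", ids, "\n", bases, "\n+\n", qual, "\n", collapse = "")
    })
}

# random pipeline over the op catalogue, respecting format constraints
randomPipelineString <- function(format) {
    pool <- list(
        function() sprintf("length:min=%d", sample(1:30, 1)),
        function() sprintf("length:max=%d", sample(40:90, 1)),
        function() "noniupac",
        function() sprintf("basecount:bases=%s,max=%d",
                           sample(c("T", "G", "N", "GC"), 1),
                           sample(5:40, 1)),
        function() sprintf("basepercent:bases=GC,max=%d", sample(40:90, 1)),
        function() sprintf("pattern:seq=%s,contains=%s",
                           sample(c("ACG", "TTT", "GATTACA"), 1),
                           sample(c("true", "false"), 1)),
        function() sprintf("trimleft:n=%d", sample(0:5, 1)),
        function() sprintf("trimright:n=%d", sample(0:5, 1)),
        function() sprintf("trimrightp:pct=%d", sample(0:20, 1)),
        function() sprintf("trimleftp:pct=%d", sample(0:15, 1)),
        function() sprintf("maxlen:n=%d", sample(30:80, 1)),
        function() "dnatorna",
        function() sprintf("rename:prefix=%s", sample(c("seq", "rd"), 1)))
    fastqOnly <- list(
        function() sprintf("quality:min=%d", sample(18:30, 1)),
        function() sprintf("trimqual:min=%d", sample(18:28, 1)))
    if (format == "fastq") pool <- c(pool, fastqOnly)
    k <- sample(0:3, 1)
    ops <- vapply(sample(pool, k), function(f) f(), character(1))
    if (format == "fastq" && stats::runif(1) < 0.15)
        ops <- c(ops, "fastqtofasta")   # format change, always last
    paste(ops, collapse = ",")
}
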