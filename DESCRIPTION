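Package: StreamQC
Title: Streaming Quality Control of FASTQ/FASTA Reads from Growing Files
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control of next-generation sequencing reads as a stream:
    FASTQ/FASTA files that are still being downloaded or written are followed
    on disk, complete records are extracted as they appear (paired-end mates
    synchronously), a user-configured chain of filters, trimmers and
    formatters is applied micro-batch by micro-batch, and results are written
    to append-only part files partitioned by a two-integer (iteration, worker)
    stamp so that an ordered merge reproduces exactly the output of batch
    processing of the finished file. Includes boundary-safe incremental
    FASTQ/FASTA scanners, a seeded synthetic read generator and a throttled
    slow-writer that emulates an in-progress download, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    parallel,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
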