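---
title: "Streaming quality control: model, contracts and design choices"
author: "StreamQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming quality control: model, contracts and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StreamQC)
```

## The processing model

StreamQC processes a sequencing dataset as an unbounded, append-only stream
of records rather than as a file at rest. A *reading stage* polls the input
file(s) on disk; whatever new bytes have appeared since the last poll are
appended to a carry buffer and scanned for **complete** records. Complete
records are split into contiguous, order-preserving slices across `w`
logical readers and packaged as *chunks*, each stamped with the pair
*(iteration, worker)*. A *processing stage* applies the user's chain of
filters, trimmers and formatters to each chunk independently, and a
*writing stage* appends exactly one part file per chunk under a partition
directory named after its stamp. Because the stamp total order (iteration-
major) equals the order in which record slices were cut from the input, an
ordered merge over partitions reconstructs the batch result exactly — the
package's central, test-enforced contract is that merged streaming output
is byte-identical to `runBatch()` on the finished input, for every growth
schedule, cap, worker count and chunk completion order.

Three places where the model needs care:

**Record-boundary detection.** FASTQ records here are strictly four logical
lines. A record is only emitted when all four lines are newline-terminated
and the quality length equals the bases length. The `@` character cannot be
used to find boundaries because Phred+33 legally encodes score 31 as `@`,
so a quality line can begin with it; the length equality disambiguates.
Multi-line FASTQ is rejected — it is essentially extinct in short-read
practice and would make streaming boundary detection ambiguous. FASTA
sequences may span lines, so a record's end is only confirmed by the *next*
header; the final record of a FASTA stream can be emitted only once end of
input is declared. At end of input a final FASTQ record missing only its
trailing newline is accepted; any other leftover bytes are a parse error.
A malformed record mid-stream aborts the run with a diagnostic rather than
being skipped silently: skipping would desynchronize paired files and
corrupt the equality-with-batch contract.

**Paired-end synchronization.** Mate files grow at independent rates.
Each poll scans both files, then emits only `min(n1, n2)` pairs, the i-th
record of one file with the i-th of the other, kept together in the same
chunk; surplus parsed records wait in a pending queue. If the streams end
with unequal totals the run fails with a pairing error — silent truncation
would hide upstream data corruption.

**Ordering.** Part files must never be ordered by filesystem modification
time: chunks may be processed and flushed in any order. Stamps are assigned
at read time, before any scheduling happens, and partition directory names
zero-pad both stamp components to six digits so that plain lexicographic
sorting equals the stamp order even beyond ten iterations or workers. The
test suite deliberately writes part files in a seeded random order and
checks the merged bytes are unchanged.

## Tunable parameters

* `capBytes` (default 64 MiB): maximum new bytes read per file per
  iteration. Bounds memory and keeps reading interleaved with processing;
  without it, a large backlog would be swallowed in one iteration and the
  overlap lost. One record may straddle the cap, so the per-iteration
  commitment is at most `capBytes` + one record.
* `minBytesPerWorker` (default 4 MiB) and `maxWorkers` (default: CPU
  count): the reader count for an iteration is
  `clamp(ceiling(available / minBytesPerWorker), 1, maxWorkers)` —
  deterministic, so stamps (and therefore output order) are reproducible,
  and small polls do not spawn many readers for little data.
* `pollInterval` (default 1 s) and the end-of-input rule: a stream has no
  intrinsic end, so termination must be declared. Either the input is
  registered complete (`follow = FALSE`), or an expected final byte size is
  given (`expectBytes`), or growth stops for `idleTimeout` seconds
  (default 10 s). A `tickHook` lets an in-process writer drive growth
  deterministically, which the tests use to exercise growth schedules
  without real-time sleeps.
* Pair policy: `discard-pair` (default) drops a pair when either mate fails
  a filter, keeping mate outputs synchronized; `independent` filters mates
  separately and is therefore only permitted with interleaved output.

## Operation semantics and numerical choices

* All numeric bounds are inclusive; a trimmed-to-count of exactly the
  maximum survives.
* Mean quality is the exact rational `sum(scores) / length`, compared
  unrounded against the threshold; platform-independent. The mean of a
  zero-length read is defined as 0, so an emptied read fails any positive
  minimum-quality bound rather than propagating NaN.
* Base matching is case-insensitive (`a` counts as `A`) while output
  preserves the original case, respecting soft-masking conventions.
* Percentage trims remove `floor(len * pct / 100)` bases — never more than
  the stated fraction.
* Quality trimming (`trimqual`) repeatedly removes the rightmost base while
  the read's mean quality is below the target, equivalently keeping the
  longest prefix whose mean reaches the target (possibly the empty read).
  This right-to-left interpretation of "trim to an average quality" is a
  declared choice; sliding-window trimming is a different operation and out
  of scope.
* Trimming an n-base read by more than n bases yields an empty read that is
  retained; a downstream `length` filter removes it if desired.
* `fastqtofasta` changes the effective format mid-chain, so a
  quality-dependent operation placed after it is rejected when the pipeline
  is compiled, before any data is read.
* `rename` is the one operation with global state: its index is the read's
  1-based position among survivors at the rename point, in stamp order.
  The engine threads a cumulative offset through chunks sequentially, which
  makes renamed output independent of scheduling; when a chain contains
  `rename`, forked chunk dispatch is disabled in favor of the sequential
  pass.

## Engine dispatch

Chunk *processing* is deterministic and sequential in stamp order by
default, with optional forked dispatch (`parallelDispatch = TRUE`, via
`parallel::mclapply`) for chains without order-dependent operations. Part
file *creation* is atomic (write to a temp file, rename into place), parts
are append-only, and a `_DONE` marker — the concrete end-of-stream signal —
is written only at successful finalization, so an aborted run is detectable
and the merge refuses to run on one. The correctness of the design does not
depend on dispatch order, and the tests assert exactly that by shuffling
part-write order.

## What the synthetic data does and does not emulate

`generateReads()` emulates a short-read dataset at desk scale: fixed or
uniformly varying read lengths (default 76 bp), uniform ACGT composition,
per-base quality scores from a rounded normal truncated to [2, 40] with
configurable mean (default 35; a mean near the filtering threshold of 25
makes the quality filter discard a seeded, predictable fraction), optional
per-base injection of non-IUPAC `X` bases, and positionally matched mate
identifiers in paired mode. `slowWriter()` emulates an in-progress
download: a seeded schedule of byte increments that grows the destination
monotonically until it equals the source, deliberately cutting inside
records — including between the `+` line and a quality line beginning with
`@` — and supporting asymmetric paired rates.

Deliberately *not* emulated: platform error profiles (position-dependent
quality decay, homopolymer errors), adapter contamination, duplicate
structure, and biased base composition. Passing tests therefore demonstrate
the streaming, parsing, ordering and operation semantics on structurally
realistic inputs; they say nothing about biological merit of any particular
filter threshold on real data.

## Problem sizes used by the checks

The test suite runs randomized streaming-vs-batch configurations at
10²–10⁵ reads (most draws in the hundreds-to-thousands range, single runs
at 10⁴–10⁵), byte-level boundary scans over a 1,000-read file with every
split inside the first three records plus 300 sampled positions, exhaustive
operation checks over all ~2.0 million sequences of length ≤ 8 on
{A,C,G,T,N,X} against a position-wise slicing oracle, and quality-based
operations on 10⁴ random reads. `scripts/acceptance.R` re-runs the
pipeline at 2 × 10⁴ single-end and 10⁴ paired reads. These sizes were
chosen to exercise many iterations, worker splits and cap boundaries while
keeping a full run in minutes on one core.

## Known limitations

* gzip input is supported only for complete files: re-scanning a growing
  compressed stream has no well-defined byte offsets.
* Quality encodings other than Phred+33, SAM/BAM input and color-space
  reads are out of scope, as are adapter trimming against adapter
  libraries, sliding-window quality trimming, and duplicate/complexity
  filters.
* The follower watches a local file; downloading from a remote URL is the
  job of an external process writing that file.
* Single-host execution; no distributed operation or mid-run
  checkpoint/restart.
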