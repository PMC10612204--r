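## The quality-control operation catalogue: single filters (per-record
## keep/discard predicates), trimmers and formatters, plus the pipeline
## grammar and composition. All numeric bounds are inclusive; base matching
## is case-insensitive while output preserves the original case; quality
## strings are trimmed in lockstep with bases.

#' Mean Phred+33 quality per record
#'
#' Arithmetic mean over bases of `utf8ToInt(quality char) - 33`, computed as
#' an exact integer sum divided by the length (no rounding before threshold
#' comparison). A zero-length record is assigned mean 0.
#'
#' @param records a FASTQ [SeqRecords-class].
#' @return numeric vector of mean qualities.
#' @examples
#' meanQuality(SeqRecords("r", "ACGT", "IIII"))  # 40
#' @export
meanQuality <- function(records) {
    stopifnot(is(records, "SeqRecords"), records@format == "fastq")
    vapply(records@quality, function(q) {
        s <- utf8ToInt(q)
        if (length(s) == 0L) 0 else sum(s - 33L) / length(s)
    }, numeric(1L), USE.NAMES = FALSE)
}

countBase <- function(upperBases, base) {
    nchar(upperBases, type = "bytes") -
        nchar(gsub(toupper(base), "", upperBases, fixed = TRUE),
              type = "bytes")
}

## filters: (SeqRecords) -> logical keep mask -----------------------------

#' QC filters
#'
#' Per-record keep/discard predicates, evaluated independently per record;
#' each returns a logical keep mask and never modifies records. All bounds
#' are inclusive.
#'
#' * `filterQuality`: keep records whose mean Phred+33 quality (see
#'   [meanQuality()]) lies within `[min, max]`; FASTQ only.
#' * `filterNonIupac`: keep records whose every base is one of
#'   A, T, G, C, N (case-insensitive); an empty sequence passes vacuously.
#' * `filterLength`: keep records whose base count lies within
#'   `[min, max]`.
#' * `filterBaseCount`: for every base in `bases` (e.g. `"T"` or `"GC"`),
#'   the per-base-type count must lie within `[min, max]`.
#' * `filterBasePercent`: the combined percentage of bases in `bases`
#'   (100 x count / length, 0 for an empty sequence) must lie within
#'   `[min, max]`.
#' * `filterPattern`: keep iff (the plain substring `seq` occurs in the
#'   bases) equals `contains`; matching is case-insensitive.
#'
#' @param records a [SeqRecords-class].
#' @param min,max inclusive bounds; `NULL` leaves the side unbounded (at
#'   least one must be given).
#' @param bases one or more base characters, as a string.
#' @param seq non-empty substring to look for.
#' @param contains logical: keep on presence (`TRUE`) or absence (`FALSE`).
#' @return logical keep mask, one element per record.
#' @name qc-filters
#' @examples
#' r <- SeqRecords(c("a", "b"), c("GGTTTT", "ACGT"),
#'                 c("IIIIII", "IIII"))
#' filterBaseCount(r, bases = "T", max = 3)  # FALSE TRUE
NULL

checkBounds <- function(min, max) {
    if (is.null(min) && is.null(max))
        stopQC("streamqc_config_error",
               "at least one of 'min'/'max' must be given")
}

#' @rdname qc-filters
#' @export
filterQuality <- function(records, min = NULL, max = NULL) {
    checkBounds(min, max)
    if (records@format != "fastq")
        stopQC("streamqc_config_error",
               "quality filter requires FASTQ records (no quality in FASTA)")
    mq <- meanQuality(records)
    keep <- rep(TRUE, length(records))
    if (!is.null(min)) keep <- keep & mq >= min
    if (!is.null(max)) keep <- keep & mq <= max
    keep
}

#' @rdname qc-filters
#' @export
filterNonIupac <- function(records)
    !grepl("[^ATGCNatgcn]", records@bases)

#' @rdname qc-filters
#' @export
filterLength <- function(records, min = NULL, max = NULL) {
    checkBounds(min, max)
    len <- nchar(records@bases, type = "bytes")
    keep <- rep(TRUE, length(records))
    if (!is.null(min)) keep <- keep & len >= min
    if (!is.null(max)) keep <- keep & len <= max
    keep
}

#' @rdname qc-filters
#' @export
filterBaseCount <- function(records, bases, min = NULL, max = NULL) {
    checkBounds(min, max)
    stopifnot(nzchar(bases))
    up <- toupper(records@bases)
    keep <- rep(TRUE, length(records))
    for (b in strsplit(bases, "")[[1L]]) {
        cnt <- countBase(up, b)
        if (!is.null(min)) keep <- keep & cnt >= min
        if (!is.null(max)) keep <- keep & cnt <= max
    }
    keep
}

#' @rdname qc-filters
#' @export
filterBasePercent <- function(records, bases, min = NULL, max = NULL) {
    checkBounds(min, max)
    stopifnot(nzchar(bases))
    up <- toupper(records@bases)
    len <- nchar(up, type = "bytes")
    cnt <- rep(0L, length(records))
    for (b in strsplit(bases, "")[[1L]])
        cnt <- cnt + countBase(up, b)
    pct <- ifelse(len == 0L, 0, 100 * cnt / len)
    keep <- rep(TRUE, length(records))
    if (!is.null(min)) keep <- keep & pct >= min
    if (!is.null(max)) keep <- keep & pct <= max
    keep
}

#' @rdname qc-filters
#' @export
filterPattern <- function(records, seq, contains = TRUE) {
    stopifnot(nzchar(seq))
    hit <- grepl(toupper(seq), toupper(records@bases), fixed = TRUE)
    hit == contains
}

## trimmers and formatters: (SeqRecords) -> SeqRecords --------------------

trimTo <- function(records, start, stop) {
    ## lockstep trim of bases and (when present) quality
    if (length(records) == 0L) return(records)
    bases <- substring(records@bases, start, stop)
    quality <- ifelse(is.na(records@quality), NA_character_,
                      substring(records@quality, start, stop))
    initialize(records, bases = bases, quality = quality)
}

#' QC trimmers
#'
#' Operations that shorten reads; quality strings are trimmed in lockstep
#' with bases so that the FASTQ length equality always holds. Identifiers
#' are never changed, and records are never dropped (a fully trimmed record
#' has empty bases; a downstream length filter may remove it).
#'
#' * `trimLeft` / `trimRight`: remove the first / last `min(n, length)`
#'   bases.
#' * `trimLeftPercent` / `trimRightPercent`: remove
#'   `floor(length * pct / 100)` bases from the stated end (floor, so never
#'   more than the stated fraction).
#' * `trimToMaxLength`: keep at most the first `max` bases.
#' * `trimQualityRight`: repeatedly drop the rightmost base while the
#'   record's mean quality is below `min`; stops at the first (longest)
#'   prefix whose mean reaches `min`, possibly the empty read. FASTQ only.
#'
#' @param records a [SeqRecords-class].
#' @param n number of bases to remove (or to keep, for `trimToMaxLength`'s
#'   `max`); >= 0.
#' @param pct percentage in `[0, 100]`.
#' @param max maximum read length to keep (>= 0).
#' @param min target mean Phred+33 quality.
#' @return A [SeqRecords-class] of the same length.
#' @name qc-trimmers
#' @examples
#' seqBases(trimRight(SeqRecords("r", "ACGTACG", "IIIIIII"), 3))  # "ACGT"
NULL

#' @rdname qc-trimmers
#' @export
trimLeft <- function(records, n) {
    stopifnot(n >= 0)
    trimTo(records, n + 1L, nchar(records@bases, type = "bytes"))
}

#' @rdname qc-trimmers
#' @export
trimRight <- function(records, n) {
    stopifnot(n >= 0)
    trimTo(records, 1L, pmax(nchar(records@bases, type = "bytes") - n, 0L))
}

#' @rdname qc-trimmers
#' @export
trimLeftPercent <- function(records, pct) {
    stopifnot(pct >= 0, pct <= 100)
    len <- nchar(records@bases, type = "bytes")
    trimTo(records, floor(len * pct / 100) + 1L, len)
}

#' @rdname qc-trimmers
#' @export
trimRightPercent <- function(records, pct) {
    stopifnot(pct >= 0, pct <= 100)
    len <- nchar(records@bases, type = "bytes")
    trimTo(records, 1L, len - floor(len * pct / 100))
}

#' @rdname qc-trimmers
#' @export
trimToMaxLength <- function(records, max) {
    stopifnot(max >= 0)
    trimTo(records, 1L, pmin(nchar(records@bases, type = "bytes"),
                             as.integer(max)))
}

#' @rdname qc-trimmers
#' @export
trimQualityRight <- function(records, min) {
    if (records@format != "fastq")
        stopQC("streamqc_config_error",
               "quality trimming requires FASTQ records")
    keepLen <- vapply(records@quality, function(q) {
        s <- utf8ToInt(q) - 33L
        if (length(s) == 0L) return(0L)
        ok <- which(cumsum(s) / seq_along(s) >= min)
        if (length(ok) == 0L) 0L else max(ok)
    }, integer(1L), USE.NAMES = FALSE)
    trimTo(records, 1L, keepLen)
}

#' QC formatters
#'
#' Representation changes that neither filter nor shorten reads.
#'
#' * `dnaToRna` / `rnaToDna`: replace thymine with uracil (`T -> U`) or back
#'   (`U -> T`), preserving per-character case; id and quality unchanged.
#' * `fastqToFasta`: drop the quality string and return FASTA records with
#'   identical ids and bases (identity on input that is already FASTA).
#' * `renameIds`: replace identifiers with `<prefix><index>` where `index`
#'   is the record's 1-based global position in stamp order among survivors;
#'   the streaming engine threads `start` across chunks so that merged
#'   output carries consecutive indices. In paired mode both mates get the
#'   pair's index plus a `/1` or `/2` mate suffix.
#'
#' @param records a [SeqRecords-class].
#' @param prefix identifier prefix.
#' @param start 0-based offset: the first record is numbered `start + 1`.
#' @param mateSuffix `""`, `"/1"` or `"/2"`.
#' @return A [SeqRecords-class] of the same length.
#' @name qc-formatters
#' @examples
#' seqBases(dnaToRna(SeqRecords("r", "ATGC", "IIII")))  # "AUGC"
NULL

#' @rdname qc-formatters
#' @export
dnaToRna <- function(records)
    initialize(records, bases = chartr("Tt", "Uu", records@bases))

#' @rdname qc-formatters
#' @export
rnaToDna <- function(records)
    initialize(records, bases = chartr("Uu", "Tt", records@bases))

#' @rdname qc-formatters
#' @export
fastqToFasta <- function(records) {
    if (records@format == "fasta") return(records)
    SeqRecords(records@id, records@bases, format = "fasta")
}

#' @rdname qc-formatters
#' @export
renameIds <- function(records, prefix, start = 0, mateSuffix = "") {
    if (length(records) == 0L) return(records)
    initialize(records,
               id = paste0(prefix, start + seq_len(length(records)),
                           mateSuffix))
}

## operation registry -----------------------------------------------------

.opRegistry <- new.env(parent = emptyenv())

#' Register a QC operation
#'
#' Extension point: new operations become available to [parsePipeline()],
#' [buildPipeline()] and the CLI without touching the engine.
#'
#' @param name operation identifier used in pipeline strings.
#' @param kind `"filter"` (predicate) or `"map"` (record transform).
#' @param make `function(params)` returning, for filters, a
#'   `function(records) -> logical` keep mask; for maps, a
#'   `function(records) -> records` transform (for index-using maps, a
#'   `function(records, start, mateSuffix) -> records`).
#' @param paramNames allowed parameter names.
#' @param required parameter names that must be present (`"min|max"` means
#'   at least one of the two).
#' @param requiresQuality does the op need FASTQ at its position in the
#'   chain?
#' @param newFormat format the op converts records to (`NA` if unchanged).
#' @param usesIndex does the op need the global record index (rename)?
#' @return `name`, invisibly.
#' @export
registerOp <- function(name, kind, make, paramNames = character(),
                       required = character(), requiresQuality = FALSE,
                       newFormat = NA_character_, usesIndex = FALSE) {
    stopifnot(kind %in% c("filter", "map"))
    make <- local({
        inner <- make
        function(p) { force(p); inner(p) }  # pin params per compiled step
    })
    assign(name, list(name = name, kind = kind, make = make,
                      paramNames = paramNames, required = required,
                      requiresQuality = requiresQuality,
                      newFormat = newFormat, usesIndex = usesIndex),
           envir = .opRegistry)
    invisible(name)
}

#' Names of all registered operations
#' @return character vector.
#' @export
listOps <- function() sort(ls(.opRegistry))

getOp <- function(name) {
    if (!exists(name, envir = .opRegistry, inherits = FALSE))
        stopQC("streamqc_config_error",
               "unknown operation '%s'; registered operations: %s",
               name, paste(listOps(), collapse = ", "))
    get(name, envir = .opRegistry, inherits = FALSE)
}

validateParams <- function(op, params) {
    extra <- setdiff(names(params), op$paramNames)
    if (length(extra))
        stopQC("streamqc_config_error",
               "operation '%s' does not accept parameter(s): %s",
               op$name, paste(extra, collapse = ", "))
    for (req in op$required) {
        alts <- strsplit(req, "|", fixed = TRUE)[[1L]]
        if (!any(alts %in% names(params)))
            stopQC("streamqc_config_error",
                   "operation '%s' requires parameter %s", op$name,
                   paste(alts, collapse = " or "))
    }
    params
}

local({
    num <- function(p, k) if (is.null(p[[k]])) NULL else as.numeric(p[[k]])
    registerOp("quality", "filter", paramNames = c("min", "max"),
        required = "min|max", requiresQuality = TRUE,
        make = function(p) function(r)
            filterQuality(r, num(p, "min"), num(p, "max")))
    registerOp("noniupac", "filter",
        make = function(p) function(r) filterNonIupac(r))
    registerOp("length", "filter", paramNames = c("min", "max"),
        required = "min|max",
        make = function(p) function(r)
            filterLength(r, num(p, "min"), num(p, "max")))
    registerOp("basecount", "filter",
        paramNames = c("bases", "min", "max"),
        required = c("bases", "min|max"),
        make = function(p) function(r)
            filterBaseCount(r, p$bases, num(p, "min"), num(p, "max")))
    registerOp("basepercent", "filter",
        paramNames = c("bases", "min", "max"),
        required = c("bases", "min|max"),
        make = function(p) function(r)
            filterBasePercent(r, p$bases, num(p, "min"), num(p, "max")))
    registerOp("pattern", "filter", paramNames = c("seq", "contains"),
        required = "seq",
        make = function(p) function(r)
            filterPattern(r, p$seq,
                          if (is.null(p$contains)) TRUE
                          else isTRUE(p$contains)))
    registerOp("trimleft", "map", paramNames = "n", required = "n",
        make = function(p) function(r) trimLeft(r, as.numeric(p$n)))
    registerOp("trimright", "map", paramNames = "n", required = "n",
        make = function(p) function(r) trimRight(r, as.numeric(p$n)))
    registerOp("trimleftp", "map", paramNames = "pct", required = "pct",
        make = function(p) function(r) trimLeftPercent(r, as.numeric(p$pct)))
    registerOp("trimrightp", "map", paramNames = "pct", required = "pct",
        make = function(p) function(r)
            trimRightPercent(r, as.numeric(p$pct)))
    registerOp("maxlen", "map", paramNames = "n", required = "n",
        make = function(p) function(r) trimToMaxLength(r, as.numeric(p$n)))
    registerOp("trimqual", "map", paramNames = "min", required = "min",
        requiresQuality = TRUE,
        make = function(p) function(r)
            trimQualityRight(r, as.numeric(p$min)))
    registerOp("dnatorna", "map", make = function(p) function(r) dnaToRna(r))
    registerOp("rnatodna", "map", make = function(p) function(r) rnaToDna(r))
    registerOp("fastqtofasta", "map", newFormat = "fasta",
        make = function(p) function(r) fastqToFasta(r))
    registerOp("rename", "map", paramNames = "prefix", required = "prefix",
        usesIndex = TRUE,
        make = function(p) function(r, start = 0, mateSuffix = "")
            renameIds(r, p$prefix, start, mateSuffix))
})

## pipeline grammar and composition ---------------------------------------

coerceParamValue <- function(x) {
    if (grepl("^(true|false)$", x, ignore.case = TRUE))
        return(tolower(x) == "true")
    if (grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x))
        return(as.numeric(x))
    x
}

#' Parse a pipeline string
#'
#' Grammar: operations separated by `,` or `;`, applied left to right; an
#' operation is `name` or `name:key=value`, with further `key=value` tokens
#' attaching to the most recent operation. Example:
#' `"trimright:n=3,basecount:bases=T,max=3"` is the trim-then-count chain of
#' a two-operation run. `true`/`false` and numbers are coerced.
#'
#' @param x pipeline string (or an already-parsed [PipelineSpec-class],
#'   returned unchanged).
#' @return A [PipelineSpec-class].
#' @examples
#' parsePipeline("quality:min=25,trimrightp:pct=10")
#' @export
parsePipeline <- function(x) {
    if (is(x, "PipelineSpec")) return(x)
    stopifnot(is.character(x), length(x) == 1L)
    tokens <- trimws(strsplit(x, "[,;]")[[1L]])
    tokens <- tokens[nzchar(tokens)]
    ops <- list()
    for (tok in tokens) {
        if (grepl(":", tok, fixed = TRUE) || !grepl("=", tok, fixed = TRUE)) {
            nm <- sub(":.*$", "", tok)
            ops[[length(ops) + 1L]] <- list(name = nm, params = list())
            rest <- if (grepl(":", tok, fixed = TRUE))
                sub("^[^:]*:", "", tok) else ""
            tok <- rest
            if (!nzchar(tok)) next
        }
        if (length(ops) == 0L)
            stopQC("streamqc_config_error",
                   "pipeline parameter '%s' precedes any operation", tok)
        kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
            stopQC("streamqc_config_error",
                   "cannot parse pipeline token '%s'", tok)
        ops[[length(ops)]]$params[[kv[1L]]] <- coerceParamValue(kv[2L])
    }
    new("PipelineSpec", ops = ops)
}

#' Compile a pipeline specification into an executable plan
#'
#' Validates every operation (known name, parameter schema) and checks
#' format compatibility along the chain: quality-dependent operations
#' require FASTQ at their position, and a `fastqtofasta` conversion changes
#' the effective format for everything downstream -- so e.g. a quality
#' filter after it is rejected at build time, before any data is touched.
#'
#' @param spec a [PipelineSpec-class] or pipeline string
#'   (see [parsePipeline()]).
#' @param inputFormat `"fastq"` or `"fasta"`.
#' @param pairPolicy `"discard-pair"`: a pair survives a filter only if
#'   both mates pass (keeps mate files synchronized); `"independent"`:
#'   mates are filtered separately, which can desynchronize counts and is
#'   therefore only allowed with interleaved output.
#' @return A `PipelinePlan` (list with compiled steps and the effective
#'   output format).
#' @seealso [applyPipeline()], [runStream()]
#' @export
buildPipeline <- function(spec, inputFormat = "fastq",
                          pairPolicy = c("discard-pair", "independent")) {
    spec <- parsePipeline(spec)
    pairPolicy <- match.arg(pairPolicy)
    inputFormat <- match.arg(inputFormat, c("fastq", "fasta"))
    fmt <- inputFormat
    steps <- vector("list", length(spec@ops))
    for (i in seq_along(spec@ops)) {
        o <- spec@ops[[i]]
        op <- getOp(o$name)
        params <- validateParams(op, o$params)
        if (op$requiresQuality && fmt != "fastq")
            stopQC("streamqc_config_error",
                   "operation '%s' (position %d) needs quality scores but the records are %s at that point in the chain",
                   op$name, i, toupper(fmt))
        steps[[i]] <- list(name = op$name, kind = op$kind,
                           fn = op$make(params), usesIndex = op$usesIndex)
        if (!is.na(op$newFormat)) fmt <- op$newFormat
    }
    structure(list(steps = steps, inputFormat = inputFormat,
                   outputFormat = fmt, pairPolicy = pairPolicy,
                   hasRename = any(vapply(steps, `[[`, TRUE, "usesIndex"))),
              class = "PipelinePlan")
}

#' @export
print.PipelinePlan <- function(x, ...) {
    cat(sprintf("PipelinePlan: %d step(s), %s -> %s\n", length(x$steps),
                toupper(x$inputFormat), toupper(x$outputFormat)))
    invisible(x)
}

#' Apply a compiled pipeline to a batch of records
#'
#' Operations are applied strictly in order. Filters drop records (and
#' count what they drop); maps transform records one-for-one. For record
#' pairs under the `discard-pair` policy, a pair survives a filter only if
#' both mates pass it, while maps apply to each mate independently. The
#' `index` offset is threaded through for position-dependent operations
#' (identifier renaming): it is the number of records (pairs) that survived
#' up to the rename point in all earlier chunks in stamp order.
#'
#' @param plan a plan from [buildPipeline()].
#' @param records a [SeqRecords-class] (mate 1 in paired mode).
#' @param second mate 2 records for paired input, or `NULL`.
#' @param index 0-based global offset for index-using operations.
#' @return list with `records` (and `second` when paired) of survivors,
#'   `discards` (named counts per filter, pairs counted as 2 records) and
#'   `nextIndex` (offset to pass for the following chunk).
#' @export
applyPipeline <- function(plan, records, second = NULL, index = 0) {
    stopifnot(inherits(plan, "PipelinePlan"))
    paired <- !is.null(second)
    perRec <- if (paired) 2L else 1L
    discards <- structure(numeric(0), names = character(0))
    nextIndex <- index
    for (st in plan$steps) {
        if (st$kind == "filter") {
            keep <- st$fn(records)
            if (paired) keep <- keep & st$fn(second)
            dropped <- sum(!keep) * perRec
            discards[st$name] <-
                (if (is.na(discards[st$name])) 0 else discards[st$name]) +
                dropped
            records <- records[keep]
            if (paired) second <- second[keep]
        } else if (st$usesIndex) {
            n <- length(records)
            if (paired) {
                records <- st$fn(records, index, "/1")
                second <- st$fn(second, index, "/2")
            } else records <- st$fn(records, index)
            nextIndex <- index + n
        } else {
            records <- st$fn(records)
            if (paired) second <- st$fn(second)
        }
    }
    if (!plan$hasRename) nextIndex <- index + length(records)
    list(records = records, second = if (paired) second,
         discards = discards, nextIndex = nextIndex)
}
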