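#' @importFrom stats median quantile rbinom rnorm runif rpois setNames
#'   complete.cases cor dchisq lm na.omit p.adjust pchisq pnorm prcomp
#'   fisher.test dhyper var sd rgamma
#' @importFrom utils head tail write.table read.table
#' @import data.table
NULL

# Derive a reproducible sub-seed for a named stage from the master seed.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() never overflows.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647)
  for (cc in codes) h <- (h * 31 + cc) %% 2147483629
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under the RNG substream `name` of `seed`, restoring the
# caller's RNG state afterwards so stages can be re-run independently.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, name))
  expr
}

#' Format a proportion as a percentage with round-half-even
#'
#' Reporting helper used for catalogue summaries: percentages are printed
#' to one decimal using banker's rounding, the convention adopted for all
#' summary tables in this package.
#'
#' @param x numerator (count) or proportion if `total` is missing.
#' @param total denominator; if supplied the percentage is `100 * x/total`.
#' @param digits decimal places (default 1).
#' @return numeric percentage rounded to `digits` decimals.
#' @export
pct_round <- function(x, total = NULL, digits = 1) {
  p <- if (is.null(total)) 100 * x else 100 * x / total
  round(p, digits) # base round() is IEC 60559 round-half-even
}

# Length of the union of 0-based half-open intervals, via IRanges.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Reverse complement of a plain character sequence.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Random DNA of length n at a given GC content (vector draw, caller seeds).
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Lexicographically least rotation of a motif (canonical tandem motif).
canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n <= 1L) return(motif)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1, i - 1L)), character(1))
  sort(rots)[1L]
}

# Primitive root of a motif: smallest period that tiles it exactly.
primitive_motif <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    unit <- substr(motif, 1L, p)
    if (strrep(unit, n %/% p) == motif) return(unit)
  }
  motif
}

`%||%` <- function(a, b) if (is.null(a)) b else a
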