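#' Tandem repeat, satellite and low-complexity annotation
#'
#' Built-in desk-scale detectors standing in for external repeat engines.
#' Annotations are data frames with columns `start`, `end` (0-based
#' half-open on the annotated sequence), `class` (`"STR"`, `"VNTR"`,
#' `"satellite"`, `"low_complexity"`), `motif` and `copies`.
#'
#' @name seqcore-repeats
NULL

repeat_annotation <- function(start = integer(), end = integer(),
                              class = character(), motif = character(),
                              copies = numeric()) {
  data.frame(start = as.integer(start), end = as.integer(end),
             class = class, motif = motif, copies = as.numeric(copies),
             stringsAsFactors = FALSE)
}

#' Detect maximal tandem arrays by shift periodicity
#'
#' For each candidate period p the sequence is compared with itself shifted
#' by p; maximal agreement runs (allowing short interruptions, overall unit
#' identity >= `min_identity`) with at least `min_copies` copies are
#' reported.  Smaller periods take precedence: an array already explained
#' by a smaller period is not re-reported at its multiples.  The motif is
#' reported as the lexicographically least rotation of the primitive unit.
#'
#' @param seq character scalar (length >= 2).
#' @param max_period largest motif length considered (default 100).
#' @param min_copies minimum (fractional) copy number (default 5).
#' @param min_identity minimum agreement fraction within an array.
#' @return annotation data frame; class `"STR"` for motifs of 1-6 bp,
#'   `"VNTR"` for motifs >= 7 bp.
#' @export
scan_tandem_repeats <- function(seq, max_period = 100L, min_copies = 5,
                                min_identity = 0.8) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  stopifnot(n >= 2L)
  chars <- utf8ToInt(seq)
  cand <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    if (n < min_copies * p) break
    # cheap subsampled prefilter: a qualifying array raises the global
    # agreement fraction at shift p well above the ~0.25 random baseline;
    # shifts that cannot host an array covering >= ~25% of the sequence
    # are skipped without the full scan
    if (n - p > 512L) {
      sub <- seq.int(1L, n - p, by = 8L)
      if (mean(chars[sub] == chars[sub + p]) < 0.40) next
    }
    eq <- chars[seq_len(n - p)] == chars[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge TRUE runs across short FALSE interruptions (<= 20% of a unit)
    idx <- which(r$values)
    if (length(idx) == 0L) next
    ts <- starts[idx]; te <- ends[idx]
    tol <- max(1L, ceiling(0.2 * p))
    grp <- cumsum(c(1L, (ts[-1] - te[-length(te)] - 1L) > tol))
    ms <- tapply(ts, grp, min); me <- tapply(te, grp, max)
    # only spans long enough to qualify are examined further
    ok <- (me - ms + 1L + p) >= min_copies * p
    merged <- Map(c, ms[ok], me[ok])
    for (mr in merged) {
      span <- mr[2] - mr[1] + 1L
      arr_len <- span + p            # run of i..j agreement covers i..j+p
      if (arr_len < min_copies * p) next
      frac <- mean(eq[mr[1]:mr[2]])
      if (frac < min_identity) next
      a0 <- mr[1] - 1L; a1 <- mr[2] + p   # 0-based half-open
      unit <- substr(seq, a0 + 1L, a0 + p)
      prim <- primitive_motif(unit)
      motif <- canonical_rotation(prim)
      cand[[length(cand) + 1L]] <- list(a0 = a0, a1 = a1, p = p,
                                        motif = motif, len = arr_len)
    }
  }
  if (length(cand) == 0L) return(repeat_annotation())
  # greedy selection, longest array first (smaller period breaks ties), so
  # arrays re-detected at period multiples or via internal sub-runs are
  # suppressed once >= 90% of their span is already explained
  ord <- order(-vapply(cand, `[[`, 0, "len"), vapply(cand, `[[`, 0, "p"))
  covered <- logical(n)
  out <- list()
  for (i in ord) {
    cc <- cand[[i]]
    if (mean(covered[(cc$a0 + 1L):cc$a1]) >= 0.9) next
    pl <- nchar(cc$motif)
    out[[length(out) + 1L]] <- repeat_annotation(
      cc$a0, cc$a1, if (pl <= 6) "STR" else "VNTR", cc$motif, cc$len / pl)
    covered[(cc$a0 + 1L):cc$a1] <- TRUE
  }
  ann <- do.call(rbind, out)
  ann[order(ann$start, ann$end), , drop = FALSE]
}

#' Mask annotated intervals and report the masked fraction
#'
#' @param seq character scalar.
#' @param annotations annotation data frame (see [scan_tandem_repeats()]).
#' @param classes which annotation classes to mask (default: all present).
#' @return list with `masked` (sequence with masked bases as `N`) and
#'   `fraction` (union length of selected intervals / sequence length).
#' @export
mask_and_fraction <- function(seq, annotations,
                              classes = unique(annotations$class)) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  ann <- annotations[annotations$class %in% classes, , drop = FALSE]
  if (nrow(ann) == 0L) return(list(masked = seq, fraction = 0))
  s <- pmax(0L, pmin(ann$start, n))
  e <- pmax(0L, pmin(ann$end, n))
  keep <- e > s
  if (!any(keep)) return(list(masked = seq, fraction = 0))
  ir <- IRanges::reduce(IRanges::IRanges(s[keep] + 1L, e[keep]))
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_along(ir))
    chars[BiocGenerics::start(ir)[i]:BiocGenerics::end(ir)[i]] <- "N"
  list(masked = paste(chars, collapse = ""),
       fraction = sum(IRanges::width(ir)) / n)
}

#' Match a sequence against a satellite monomer library
#'
#' k-mer matching against doubled library monomers (both strands), with
#' hits chained into intervals merged within one monomer length.
#'
#' @param seq character scalar.
#' @param satellite_library named character vector or `DNAStringSet` of
#'   monomer sequences.
#' @param k matching k-mer length (default 13).
#' @param lib_kmers precomputed [satellite_kmer_sets()] output (computed
#'   when missing; precompute when screening many sequences).
#' @return annotation data frame with class `"satellite"`.
#' @export
match_satellites <- function(seq, satellite_library, k = 13L,
                             lib_kmers = NULL) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  lib <- as_target_seqs(satellite_library)
  if (n < k || length(lib) == 0L) return(repeat_annotation())
  if (is.null(lib_kmers)) lib_kmers <- satellite_kmer_sets(lib, k)
  out <- list()
  pos <- seq_len(n - k + 1L)
  seq_kmers <- substring(seq, pos, pos + k - 1L)
  for (nm in names(lib)) {
    mon <- lib[[nm]]
    ml <- nchar(mon)
    hit <- which(seq_kmers %in% lib_kmers[[nm]])
    if (length(hit) == 0L) next
    # merge hit k-mers (covering [hit-1, hit-1+k)) within one monomer
    h0 <- hit - 1L
    brk <- c(TRUE, diff(h0) > ml + k)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      hh <- h0[grp == g]
      a0 <- min(hh); a1 <- max(hh) + k
      if (a1 - a0 < ml) next
      out[[length(out) + 1L]] <- repeat_annotation(
        a0, a1, "satellite", nm, (a1 - a0) / ml)
    }
  }
  if (length(out) == 0L) return(repeat_annotation())
  ann <- do.call(rbind, out)
  ann[order(ann$start, ann$end), , drop = FALSE]
}

#' Precompute k-mer sets of doubled satellite monomers (both strands)
#'
#' @param satellite_library monomer library.
#' @param k k-mer length.
#' @return named list of character k-mer vectors, one per monomer.
#' @export
satellite_kmer_sets <- function(satellite_library, k = 13L) {
  lib <- as_target_seqs(satellite_library)
  lapply(lib, function(mon) {
    ml <- nchar(mon)
    dd <- paste0(mon, substr(mon, 1L, min(ml, k - 1L)))
    mp <- seq_len(nchar(dd) - k + 1L)
    kms <- substring(dd, mp, mp + k - 1L)
    rc <- revcomp(dd)
    kms2 <- substring(rc, mp, mp + k - 1L)
    unique(c(kms, kms2))
  })
}

#' Flag low-complexity windows by base composition
#'
#' Windows where the two most frequent bases account for at least
#' `max_two_base` of positions are flagged and merged.
#'
#' @param seq character scalar.
#' @param window,step sliding window size and step in bp.
#' @param max_two_base threshold on the two-base fraction (default 0.9).
#' @return annotation data frame with class `"low_complexity"`.
#' @export
scan_low_complexity <- function(seq, window = 64L, step = 32L,
                                max_two_base = 0.9) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  if (n < window) return(repeat_annotation())
  chars <- utf8ToInt(seq)
  starts <- unique(c(seq(0L, n - window, by = step), n - window))
  counts <- vapply(utf8ToInt("ACGT"), function(b) {
    cs <- c(0L, cumsum(chars == b))
    cs[starts + window + 1L] - cs[starts + 1L]
  }, numeric(length(starts)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  sorted <- t(apply(counts, 1L, sort, decreasing = TRUE))
  flag <- (sorted[, 1L] + sorted[, 2L]) / window >= max_two_base
  if (!any(flag)) return(repeat_annotation())
  ir <- IRanges::reduce(IRanges::IRanges(starts[flag] + 1L,
                                         starts[flag] + window))
  repeat_annotation(BiocGenerics::start(ir) - 1L, BiocGenerics::end(ir),
                    "low_complexity", NA_character_, NA_real_)
}
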