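#' Pairwise alignment primitives
#'
#' Desk-scale replacement for an external long-read/contig aligner.
#' [align_pair()] performs k-mer seeded, window-restricted affine-gap
#' alignment of a query against one or more target sequences and returns a
#' table of alignment records.  Short queries are aligned with full dynamic
#' programming on the seeded window; long queries fall back to colinear
#' seed chaining with per-gap dynamic programming, which is exact on the
#' mostly-identical sequences this package manipulates.
#'
#' Conventions used everywhere in the package: coordinates are 0-based
#' half-open; identity = matches / alignment columns (gap columns
#' included); coverage = aligned query bases / query length.
#'
#' @name seqcore-align
NULL

ALN_COLS <- c("query_id", "qstart", "qend", "target_id", "tstart", "tend",
              "strand", "aln_len", "identity", "coverage", "score")

empty_alignments <- function() {
  data.frame(query_id = character(), qstart = integer(), qend = integer(),
             target_id = character(), tstart = integer(), tend = integer(),
             strand = character(), aln_len = integer(),
             identity = numeric(), coverage = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

as_target_seqs <- function(target) {
  if (inherits(target, "nrs_target_index")) return(target$seqs)
  if (inherits(target, "nrs_reference")) target <- target$seqs
  if (is(target, "DNAStringSet")) {
    s <- as.character(target)
    if (is.null(names(s))) names(s) <- paste0("target", seq_along(s))
    return(s)
  }
  nm <- names(target)
  s <- toupper(as.character(target))   # as.character() drops names
  names(s) <- nm
  if (is.null(names(s))) names(s) <- if (length(s) == 1L) "target" else
    paste0("target", seq_along(s))
  s
}

#' Build a k-mer index over target sequences
#'
#' @param target named character vector, `DNAStringSet` or reference object.
#' @param k seed length (default 15).
#' @param max_occ k-mers occurring more than this often across the target
#'   are dropped from the index (repeat masking at seeding level; default
#'   32).  Repetitive regions then surface as unaligned sequence and are
#'   handled by the satellite/repeat filters.
#' @return an object of class `nrs_target_index` reusable across
#'   [align_pair()] calls.
#' @export
build_target_index <- function(target, k = 15L, max_occ = 32L) {
  seqs <- as_target_seqs(target)
  tabs <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    km <- substring(s, pos, pos + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = km[keep], chrom = nm, tpos = pos[keep] - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  dt <- dt[, if (.N <= max_occ) .SD, by = kmer]
  data.table::setkey(dt, kmer)
  structure(list(seqs = seqs, k = as.integer(k), dt = dt),
            class = "nrs_target_index")
}

.submat_cache <- new.env(parent = emptyenv())

aln_substitution_matrix <- function(match = 2, mismatch = -1) {
  key <- paste(match, mismatch)
  got <- .submat_cache[[key]]
  if (!is.null(got)) return(got)
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = FALSE,
                                                type = "DNA")
  .submat_cache[[key]] <- m
  m
}

# Alignment stats from a PairwiseAlignments object (single alignment).
pa_stats <- function(pa, nq) {
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  matches <- Biostrings::nmatch(pa)
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  ps <- BiocGenerics::start(p); pe <- BiocGenerics::end(p)
  list(qstart = ps - 1L,
       qend = pe,
       tstart = BiocGenerics::start(s) - 1L,
       tend = BiocGenerics::end(s),
       aln_len = cols,
       identity = if (cols > 0) matches / cols else 0,
       coverage = (pe - ps + 1L) / nq,
       score = Biostrings::score(pa))
}

# Seed hits of one query orientation against the index.
seed_hits <- function(qs, index, stride) {
  k <- index$k
  nq <- nchar(qs)
  if (nq < k) return(NULL)
  qpos <- unique(c(seq(1L, nq - k + 1L, by = stride), nq - k + 1L))
  km <- substring(qs, qpos, qpos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  if (!any(keep)) return(NULL)
  qdt <- data.table::data.table(kmer = km[keep], qpos = qpos[keep] - 1L)
  hits <- index$dt[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag := tpos - qpos]
  hits
}

# Cluster seed hits on (chrom, diagonal band); returns candidate loci.
cluster_hits <- function(hits, band, max_candidates) {
  data.table::setorder(hits, chrom, diag, tpos)
  hits[, grp := cumsum(c(1L, diff(diag) > band)), by = chrom]
  cand <- hits[, .(n_seeds = .N,
                   qmin = min(qpos), qmax = max(qpos),
                   tmin = min(tpos), tmax = max(tpos),
                   diag0 = as.integer(median(diag))),
               by = .(chrom, grp)]
  data.table::setorder(cand, -n_seeds)
  head(cand, max_candidates)
}

# Longest colinear chain of seed hits (increasing qpos and tpos).
# Hits are assumed within one diagonal band already; greedy works there.
chain_colinear <- function(h) {
  data.table::setorder(h, qpos, tpos)
  keep <- logical(nrow(h))
  lastq <- -1L; lastt <- -1L
  for (i in seq_len(nrow(h))) {
    if (h$qpos[i] > lastq && h$tpos[i] > lastt) {
      keep[i] <- TRUE; lastq <- h$qpos[i]; lastt <- h$tpos[i]
    }
  }
  h[keep]
}

# Piecewise alignment of a long query from a chained set of anchors.
# Splits the chain where query/target gap sizes diverge by more than
# `split_gap` (insertion/deletion breakpoints; kept below the minimum
# segment length so no plantable insertion is absorbed into a block) and
# emits one record per block.
chain_align_blocks <- function(qs, tseq, chain, k, band, submat,
                               gap_open, gap_ext, split_gap = 40L) {
  n <- nrow(chain)
  brk <- c(TRUE, (chain$qpos[-1] - chain$qpos[-n] > 10000) |
             abs((chain$qpos[-1] - chain$qpos[-n]) -
                 (chain$tpos[-1] - chain$tpos[-n])) > split_gap)
  block <- cumsum(brk)
  out <- list()
  for (b in unique(block)) {
    ch <- chain[block == b]
    m <- nrow(ch)
    q0 <- ch$qpos[1]; q1 <- ch$qpos[m] + k
    t0 <- ch$tpos[1]; t1 <- ch$tpos[m] + k
    # indel-free fast path: one vectorised whole-block comparison
    if (q1 - q0 == t1 - t0 &&
        all((ch$qpos - q0) == (ch$tpos - t0))) {
      qi <- utf8ToInt(substr(qs, q0 + 1L, q1))
      ti <- utf8ToInt(substr(tseq, t0 + 1L, t1))
      eq <- sum(qi == ti)
      len <- q1 - q0
      out[[length(out) + 1L]] <- list(
        qstart = q0, qend = q1, tstart = t0, tend = t1,
        aln_len = as.integer(len), identity = eq / len,
        score = 2 * eq - 4 * (len - eq))
      next
    }
    matches <- 0; columns <- 0; score <- 0
    # anchor k-mers match exactly
    prevq <- q0; prevt <- t0
    for (i in seq_len(m)) {
      qg <- ch$qpos[i] - prevq; tg <- ch$tpos[i] - prevt
      if (qg > 0 || tg > 0) {
        qsub <- substr(qs, prevq + 1L, ch$qpos[i])
        tsub <- substr(tseq, prevt + 1L, ch$tpos[i])
        if (qg == tg) {
          eq <- sum(strsplit(qsub, "")[[1]] == strsplit(tsub, "")[[1]])
          matches <- matches + eq; columns <- columns + qg
          score <- score + 2 * eq - (qg - eq)
        } else if (max(qg, tg) <= 5000 && min(qg, tg) >= 0) {
          if (qg == 0L || tg == 0L) {
            g <- max(qg, tg)
            columns <- columns + g
            score <- score - gap_open - gap_ext * g
          } else {
            pa <- Biostrings::pairwiseAlignment(
              qsub, tsub, type = "global", substitutionMatrix = submat,
              gapOpening = gap_open, gapExtension = gap_ext)
            st <- pa_stats(pa, qg)
            matches <- matches + st$identity * st$aln_len
            columns <- columns + st$aln_len
            score <- score + st$score
          }
        } else { # very large indel inside a block: conservative accounting
          columns <- columns + max(qg, tg)
        }
      }
      # the anchor itself
      matches <- matches + k; columns <- columns + k; score <- score + 2 * k
      prevq <- ch$qpos[i] + k; prevt <- ch$tpos[i] + k
    }
    out[[length(out) + 1L]] <- list(
      qstart = q0, qend = q1, tstart = t0, tend = t1,
      aln_len = as.integer(columns),
      identity = if (columns > 0) matches / columns else 0,
      score = score)
  }
  out
}

#' Direct pairwise similarity of two short sequences
#'
#' Full global-local dynamic programming (query global, subject local)
#' with no seeding, so highly repetitive sequences -- whose k-mers a
#' seeded index drops -- are still comparable.  Intended for
#' verification-sized inputs (product of lengths capped at 25M cells).
#'
#' @param query,subject character scalars.
#' @param match,mismatch,gap_open,gap_ext scoring (penalties positive).
#' @return one-row alignment data frame (see [align_pair()]).
#' @export
seq_similarity <- function(query, subject, match = 2, mismatch = -4,
                           gap_open = 4, gap_ext = 1) {
  query <- toupper(as.character(query)[1])
  subject <- toupper(as.character(subject)[1])
  nq <- nchar(query); ns <- nchar(subject)
  stopifnot(nq > 0L, ns > 0L)
  if (as.double(nq) * ns > 25e6)
    stop("seq_similarity() is for verification-sized sequences")
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "global-local",
    substitutionMatrix = aln_substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  st <- pa_stats(pa, nq)
  data.frame(query_id = "query", qstart = st$qstart, qend = st$qend,
             target_id = "subject", tstart = st$tstart, tend = st$tend,
             strand = "+", aln_len = st$aln_len, identity = st$identity,
             coverage = st$coverage, score = st$score,
             stringsAsFactors = FALSE)
}

#' Align a query sequence to a target
#'
#' @param query character scalar (A/C/G/T/N) or named character of length 1.
#' @param target target sequence(s), reference object, or a prebuilt
#'   [build_target_index()] index (recommended inside loops).
#' @param mode `"glocal"` (whole query must align; used for flanks and
#'   catalogue sequences) or `"local"`.
#' @param k seed length; `band` diagonal band; `stride` seed sampling step.
#' @param max_candidates number of seeded loci to extend.
#' @param match,mismatch,gap_open,gap_ext affine scoring (defaults 2/-4,
#'   open 4, extend 1; stiff penalties keep local flank alignments from
#'   drifting across insertion junctions; penalties positive).
#' @param both_strands also search the reverse complement (default TRUE).
#' @param min_seeds minimum seed hits to attempt extension.
#' @return data.frame of alignment records ordered by (score desc, target
#'   position asc); zero rows when nothing aligns.
#' @export
align_pair <- function(query, target, mode = c("glocal", "local"),
                       k = 15L, band = 64L, stride = NULL,
                       max_candidates = 8L, match = 2, mismatch = -4,
                       gap_open = 4, gap_ext = 1, both_strands = TRUE,
                       min_seeds = 1L,
                       method = c("auto", "dp", "chain")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  qname <- names(query) %||% "query"
  query <- toupper(as.character(query)[1])
  if (is.na(query) || nchar(query) == 0L) stop("empty query sequence")
  if (grepl("[^ACGTN]", query)) stop("query contains non-ACGTN characters")
  nq <- nchar(query)
  if (gsub("N", "", query, fixed = TRUE) == "") return(empty_alignments())
  index <- if (inherits(target, "nrs_target_index")) target else
    build_target_index(target, k = k)
  k <- index$k
  if (method == "auto") method <- if (nq <= 12000L) "dp" else "chain"
  if (is.null(stride))
    stride <- if (method == "chain") 25L else max(1L, k %/% 2L)
  submat <- aln_substitution_matrix(match, mismatch)
  res <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    if (strand == "-" && length(res) > 0L) {
      # strand short-circuit: if the plus strand already explains almost
      # the whole query there is nothing left for the reverse strand
      done <- do.call(rbind, res)
      cov <- interval_union_length(done$qstart, done$qend) / nq
      if (cov >= 0.90 && all(done$identity >= 0.9)) break
    }
    qs <- if (strand == "+") query else revcomp(query)
    hits <- seed_hits(qs, index, stride)
    if (is.null(hits)) next
    cand <- cluster_hits(hits, band, max_candidates)
    for (ci in seq_len(nrow(cand))) {
      cd <- cand[ci]
      if (cd$n_seeds < min_seeds) next
      tseq <- index$seqs[[cd$chrom]]
      nt <- nchar(tseq)
      if (method == "dp") {
        pad <- band + 2L * k
        w0 <- max(0L, cd$diag0 - pad)
        w1 <- min(nt, cd$diag0 + nq + pad)
        if (w1 - w0 < k) next
        wseq <- substr(tseq, w0 + 1L, w1)
        type <- if (mode == "glocal") "global-local" else "local"
        pa <- Biostrings::pairwiseAlignment(
          qs, wseq, type = type, substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_ext)
        st <- pa_stats(pa, nq)
        st$tstart <- st$tstart + w0; st$tend <- st$tend + w0
        blocks <- list(st)
      } else {
        h <- hits[chrom == cd$chrom & abs(diag - cd$diag0) <= band]
        ch <- chain_colinear(h)
        if (nrow(ch) == 0L) next
        blocks <- chain_align_blocks(qs, tseq, ch, k, band, submat,
                                     gap_open, gap_ext)
        for (i in seq_along(blocks)) {
          blocks[[i]]$coverage <-
            (blocks[[i]]$qend - blocks[[i]]$qstart) / nq
        }
      }
      for (st in blocks) {
        qst <- st$qstart; qen <- st$qend
        if (strand == "-") { qst <- nq - st$qend; qen <- nq - st$qstart }
        res[[length(res) + 1L]] <- data.frame(
          query_id = qname, qstart = as.integer(qst), qend = as.integer(qen),
          target_id = cd$chrom, tstart = as.integer(st$tstart),
          tend = as.integer(st$tend), strand = strand,
          aln_len = as.integer(st$aln_len),
          identity = st$identity, coverage = st$coverage, score = st$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) return(empty_alignments())
  out <- do.call(rbind, res)
  # de-duplicate near-identical records from adjacent candidate windows
  key <- paste(out$target_id, out$strand, round(out$tstart / 50),
               round(out$qstart / 50))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(-out$score, out$target_id, out$tstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}
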