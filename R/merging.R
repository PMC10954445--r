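#' Cluster placed calls by insertion point
#'
#' Per chromosome, single-linkage clustering of insertion points with a
#' 250 bp link distance, followed by farthest-point splitting so every
#' pairwise distance within a cluster is at most 250 bp: when a cluster's
#' diameter exceeds the bound, its two extreme points seed two clusters
#' and every point joins the nearer seed (ties to the lower seed), then
#' each side is re-checked.  Within a cluster, each sample keeps only its
#' call closest to the cluster median.
#'
#' @param calls placed-call data frame (`sample`, `seq`, `chrom`, `pos`).
#' @param max_dist pairwise distance bound in bp (default 250).
#' @return list of clusters; each is a list with `members` (data frame)
#'   and `median_pos`.
#' @export
cluster_placed <- function(calls, max_dist = 250L) {
  out <- list()
  for (chrom in unique(calls$chrom)) {
    cc <- calls[calls$chrom == chrom, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    # single linkage: break where adjacent gap exceeds the bound
    grp <- cumsum(c(1L, diff(cc$pos) > max_dist))
    for (g in unique(grp)) {
      sub <- cc[grp == g, , drop = FALSE]
      for (part in split_diameter(sub$pos, max_dist)) {
        members <- sub[part, , drop = FALSE]
        med <- floor(median(members$pos))
        # one member per sample: the call closest to the median
        keep <- unlist(lapply(split(seq_len(nrow(members)),
                                    members$sample), function(ii) {
          ii[which.min(abs(members$pos[ii] - med))]
        }))
        members <- members[sort(keep), , drop = FALSE]
        out[[length(out) + 1L]] <- list(
          members = members,
          median_pos = as.integer(floor(median(members$pos))),
          chrom = chrom)
      }
    }
  }
  out
}

# Farthest-point splitting of sorted 1-D positions into index sets whose
# diameter is <= max_dist.
split_diameter <- function(pos, max_dist) {
  idx <- seq_along(pos)
  if (max(pos) - min(pos) <= max_dist) return(list(idx))
  lo <- pos[which.min(pos)]; hi <- pos[which.max(pos)]
  left <- idx[(pos - lo) <= (hi - pos)]       # ties join the lower seed
  right <- setdiff(idx, left)
  c(lapply(split_diameter(pos[left], max_dist), function(i) left[i]),
    lapply(split_diameter(pos[right], max_dist), function(i) right[i]))
}

#' Select cluster representatives
#'
#' One placed catalogue record per cluster: the representative sequence
#' via [choose_representative()] (sum-of-pairs +2/-1/-0.5 scoring), the
#' insertion point as the median of member positions, supports as the
#' distinct member samples.  Clusters whose member sequences are mutually
#' divergent (mean pairwise identity proxy < 0.8 by length-normalized
#' score) are flagged multi-allelic.
#'
#' @param clusters output of [cluster_placed()].
#' @return data frame of placed records.
#' @export
select_representatives <- function(clusters) {
  recs <- lapply(clusters, function(cl) {
    m <- cl$members
    rep <- choose_representative(m$seq)
    multi <- FALSE
    if (nrow(m) > 1L) {
      # sum-of-pairs score of the representative, normalised by the
      # perfect-match score against all others
      norm <- 2 * sum(pmin(nchar(m$seq[rep$index]),
                           nchar(m$seq[-rep$index])))
      multi <- rep$scores[rep$index] < 0.8 * norm
    }
    data.frame(chrom = cl$chrom, pos = cl$median_pos,
               seq = rep$representative,
               rep_sample = m$sample[rep$index],
               tie_break = rep$tie_break,
               n_supports = length(unique(m$sample)),
               supports = paste(sort(unique(m$sample)), collapse = ","),
               multi_allelic = multi, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# Best alignment between two specific sequences: direct DP when the
# problem is verification-sized, seeded alignment otherwise (large
# repetitive remnants; a missed edge there only affects sequences the
# repeat filters remove anyway).
pair_match <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (as.double(nchar(a)) * nchar(b) <= 25e6) return(seq_similarity(a, b))
  aln <- align_pair(a, stats::setNames(b, "b"), mode = "glocal")
  if (nrow(aln) == 0L) return(NULL)
  aln[1L, ]
}

# Cross-sample match graph over unplaced sequences: edges between pairs
# whose best alignment has length >= min_len and identity >= min_id.
# Returns component ids and the number of distinct individuals per
# component.  A cheap shared-k-mer prefilter avoids all-vs-all DP.
unplaced_components <- function(seqs, samples, min_len = 200L,
                                min_id = 0.90, k = 15L) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    p <- seq_len(nchar(s) - k + 1L)
    unique(substring(s, p, p + k - 1L))
  })
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(intersect(kmers[[i]], kmers[[j]])) < 3L) next
    aln <- pair_match(seqs[[i]], seqs[[j]])
    if (!is.null(aln) && aln$aln_len >= min_len &&
        aln$identity >= min_id) union2(i, j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  tab <- tapply(samples, comp, function(s) length(unique(s)))
  list(component = comp,
       n_individuals = setNames(as.integer(tab), names(tab)))
}

#' Merge unplaced calls into nonredundant records
#'
#' Builds the all-vs-all match graph (alignment length >= 200 bp,
#' identity >= 0.90); within each connected component, iteratively
#' removes the shorter sequence of any matched pair whose alignment
#' covers at least 80% of either sequence; survivors become records.
#' Components observed in only one individual are dropped.
#'
#' @param calls unplaced data frame (`sample`, `seq`).
#' @param min_len,min_id,min_cov match criteria.
#' @return data frame of unplaced records (`seq`, `n_supports`,
#'   `supports`).
#' @export
merge_unplaced <- function(calls, min_len = 200L, min_id = 0.90,
                           min_cov = 0.80) {
  if (nrow(calls) == 0L)
    return(data.frame(seq = character(), n_supports = integer(),
                      supports = character(), stringsAsFactors = FALSE))
  comp <- unplaced_components(calls$seq, calls$sample, min_len, min_id)
  keep_comp <- comp$n_individuals[as.character(comp$component)] >= 2L
  out <- list()
  for (g in unique(comp$component[keep_comp])) {
    ii <- which(comp$component == g)
    alive <- rep(TRUE, length(ii))
    repeat {
      removed <- FALSE
      live <- ii[alive]
      if (length(live) < 2L) break
      for (ai in seq_along(live)) {
        for (bi in seq_along(live)) {
          if (bi <= ai) next
          i <- live[ai]; j <- live[bi]
          a <- calls$seq[i]; b <- calls$seq[j]
          short <- if (nchar(a) <= nchar(b)) i else j
          qs <- calls$seq[short]
          ts <- calls$seq[if (short == i) j else i]
          aln <- pair_match(qs, ts)
          if (!is.null(aln) && aln$aln_len >= min_len &&
              aln$identity >= min_id &&
              aln$aln_len >= min_cov * nchar(qs)) {
            alive[match(short, ii)] <- FALSE
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) break
    }
    smp <- sort(unique(calls$sample[ii]))
    for (i in ii[alive]) {
      out[[length(out) + 1L]] <- data.frame(
        seq = calls$seq[i], n_supports = length(smp),
        supports = paste(smp, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq = character(), n_supports = integer(),
                      supports = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Build the nonredundant catalogue
#'
#' Stable GNRS ids are assigned to placed records in coordinate order
#' (chromosome, then position), then to unplaced records in input order.
#'
#' @param placed_records output of [select_representatives()].
#' @param unplaced_records output of [merge_unplaced()].
#' @return data frame of class `nrs_catalogue` with columns `gnrs_id`,
#'   `placed`, `chrom`, `pos`, `seq`, `length`, `n_supports`,
#'   `supports`, `multi_allelic`.
#' @export
build_catalogue <- function(placed_records,
                            unplaced_records = NULL) {
  p <- placed_records[order(placed_records$chrom, placed_records$pos), ,
                      drop = FALSE]
  recs <- data.frame(
    placed = TRUE, chrom = p$chrom, pos = p$pos, seq = p$seq,
    n_supports = p$n_supports, supports = p$supports,
    multi_allelic = p$multi_allelic, stringsAsFactors = FALSE)
  if (!is.null(unplaced_records) && nrow(unplaced_records) > 0L) {
    recs <- rbind(recs, data.frame(
      placed = FALSE, chrom = NA_character_, pos = NA_integer_,
      seq = unplaced_records$seq,
      n_supports = unplaced_records$n_supports,
      supports = unplaced_records$supports, multi_allelic = FALSE,
      stringsAsFactors = FALSE))
  }
  recs$gnrs_id <- sprintf("GNRS_%d", seq_len(nrow(recs)))
  recs$length <- nchar(recs$seq)
  recs <- recs[, c("gnrs_id", "placed", "chrom", "pos", "seq", "length",
                   "n_supports", "supports", "multi_allelic")]
  class(recs) <- c("nrs_catalogue", "data.frame")
  recs
}

#' Compare a catalogue against an external sequence set
#'
#' A record is recovered when any external sequence aligns to it with
#' length >= 200 bp, identity >= 0.90 and coverage >= 0.80 of the
#' record.
#'
#' @param catalogue `nrs_catalogue`.
#' @param external named character vector / `DNAStringSet` of external
#'   sequences.
#' @return list (recovered ids, n_recovered, recovered_bp, fraction).
#' @export
compare_catalogues <- function(catalogue, external) {
  ext <- as_target_seqs(external)
  index <- build_target_index(ext)
  rec <- vapply(seq_len(nrow(catalogue)), function(i) {
    s <- catalogue$seq[i]
    aln <- align_pair(s, index, mode = "glocal")
    hit <- nrow(aln) > 0 && any(aln$aln_len >= 200L &
                                  aln$identity >= 0.90 &
                                  aln$coverage >= 0.80)
    if (hit) return(TRUE)
    # seeded search can miss repetitive records; fall back to direct DP
    # against each external sequence of compatible size
    for (es in ext) {
      if (as.double(nchar(s)) * nchar(es) > 25e6) next
      a <- seq_similarity(s, es)
      if (a$aln_len >= 200L && a$identity >= 0.90 &&
          a$coverage >= 0.80) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(recovered = catalogue$gnrs_id[rec], n_recovered = sum(rec),
       recovered_bp = sum(catalogue$length[rec]),
       fraction = mean(rec))
}
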