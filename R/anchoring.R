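#' Anchor a raw segment to the reference by its flanks
#'
#' Up to `flank` bp of contig sequence on each side of the segment is
#' aligned to the reference.  The segment is placed when both best flank
#' alignments have aligned length > 500 bp, land on the same chromosome
#' and strand, and their reference-side inner endpoints are < 20 bp
#' apart; the insertion point is the floored midpoint of the two inner
#' endpoints.  Otherwise the segment is unplaced with a reason
#' (`flank_missing`, `flank_short`, `gap_too_large`).
#'
#' @param segment one row of the raw-segment data frame.
#' @param contigs the sample's contigs (named character).
#' @param reference reference object or prebuilt index.
#' @param flank flank length taken from the contig (default 1000).
#' @param min_flank_aln required flank alignment length (strictly greater;
#'   default 500).
#' @param max_gap maximum inner-endpoint distance (strictly less;
#'   default 20).
#' @return a list of class `nrs_placed` (`sample`, `seq`, `chrom`, `pos`,
#'   flank metadata) or `nrs_unplaced` (`sample`, `seq`, `reason`).
#' @export
anchor <- function(segment, contigs, reference, flank = 1000L,
                   min_flank_aln = 500L, max_gap = 20L) {
  index <- if (inherits(reference, "nrs_target_index")) reference else
    build_target_index(reference)
  cseq <- contigs[[segment$contig]]
  if (is.null(attr(contigs, "normalized"))) cseq <- toupper(cseq)
  n <- nchar(cseq)
  s0 <- segment$start; s1 <- segment$end
  # flanks overshoot `margin` bp into the segment: segment boundaries are
  # seed-resolution estimates, and the local flank alignment stops at the
  # true junction, giving base-accurate inner endpoints
  margin <- 50L
  up <- substr(cseq, max(1L, s0 - flank + 1L), min(n, s0 + margin))
  down <- substr(cseq, max(1L, s1 + 1L - margin), min(n, s1 + flank))
  unplaced <- function(reason)
    structure(list(sample = segment$sample, contig = segment$contig,
                   seq = segment$seq, reason = reason),
              class = "nrs_unplaced")
  if (s0 == 0L || s1 >= n || nchar(up) == 0L || nchar(down) == 0L)
    return(unplaced("flank_missing"))
  # chain-based flank alignment with per-base junction extension: exact
  # on the clean flanks this pipeline sees, and an order of magnitude
  # cheaper than full dynamic programming; minus-strand or chainless
  # flanks fall back to the full local DP.
  best_of <- function(fl, side) {
    a <- align_pair(fl, index, mode = "local", method = "chain",
                    stride = 20L)
    if (nrow(a) == 0L || a$strand[1] == "-") {
      a <- align_pair(fl, index, mode = "local")
      if (nrow(a) == 0L) return(NULL)
      return(a[order(-a$score, a$tstart), , drop = FALSE][1L, ])
    }
    a <- a[order(-a$score, a$tstart), , drop = FALSE][1L, ]
    tseq <- index$seqs[[a$target_id]]
    nfl <- nchar(fl); L <- nchar(tseq)
    e <- 0L
    if (side == "up") {
      while (a$qend + e < nfl && a$tend + e < L &&
             substr(fl, a$qend + e + 1L, a$qend + e + 1L) ==
               substr(tseq, a$tend + e + 1L, a$tend + e + 1L) && e < 200L)
        e <- e + 1L
      a$qend <- a$qend + e; a$tend <- a$tend + e
    } else {
      while (a$qstart - e > 0L && a$tstart - e > 0L &&
             substr(fl, a$qstart - e, a$qstart - e) ==
               substr(tseq, a$tstart - e, a$tstart - e) && e < 200L)
        e <- e + 1L
      a$qstart <- a$qstart - e; a$tstart <- a$tstart - e
    }
    a$aln_len <- a$aln_len + e
    a$score <- a$score + 2 * e
    a
  }
  bu <- best_of(up, "up"); bd <- best_of(down, "down")
  if (is.null(bu) || is.null(bd)) return(unplaced("flank_missing"))
  if (bu$aln_len <= min_flank_aln || bd$aln_len <= min_flank_aln)
    return(unplaced("flank_short"))
  if (bu$target_id != bd$target_id || bu$strand != bd$strand)
    return(unplaced("gap_too_large"))
  if (bu$strand == "+") { inner_u <- bu$tend; inner_d <- bd$tstart }
  else { inner_u <- bu$tstart; inner_d <- bd$tend }
  # signed reference gap between the flank images: positive = unexplained
  # reference between them (must stay < max_gap); negative = the images
  # cross, which happens when the insertion shares sequence with the
  # reference at the junction (microhomology, tandem-repeat slippage) --
  # tolerated up to the flank margin, with midpoint placement
  g <- if (bu$strand == "+") inner_d - inner_u else inner_u - inner_d
  if (g >= max_gap || -g > margin) return(unplaced("gap_too_large"))
  structure(list(sample = segment$sample, contig = segment$contig,
                 seq = segment$seq, chrom = bu$target_id,
                 pos = as.integer(floor((inner_u + inner_d) / 2)),
                 strand = bu$strand, up_len = bu$aln_len,
                 down_len = bd$aln_len,
                 gap = g),
            class = "nrs_placed")
}

#' Anchor all surviving segments of one sample
#'
#' @param segments filtered raw segments (flagged segments are skipped).
#' @param contigs,reference,... passed to [anchor()].
#' @return list with `placed` and `unplaced` data frames.
#' @export
anchor_segments <- function(segments, contigs, reference, ...) {
  index <- if (inherits(reference, "nrs_target_index")) reference else
    build_target_index(reference)
  contigs <- vapply(contigs, toupper, character(1))
  attr(contigs, "normalized") <- TRUE
  segments <- segments_pass(segments)
  placed <- list(); unplaced <- list()
  for (i in seq_len(nrow(segments))) {
    r <- anchor(segments[i, ], contigs, index, ...)
    if (inherits(r, "nrs_placed")) {
      placed[[length(placed) + 1L]] <- data.frame(
        sample = r$sample, contig = r$contig, seq = r$seq,
        chrom = r$chrom, pos = r$pos, strand = r$strand,
        up_len = r$up_len, down_len = r$down_len, gap = r$gap,
        stringsAsFactors = FALSE)
    } else {
      unplaced[[length(unplaced) + 1L]] <- data.frame(
        sample = r$sample, contig = r$contig, seq = r$seq,
        reason = r$reason, stringsAsFactors = FALSE)
    }
  }
  list(placed = if (length(placed)) do.call(rbind, placed) else
         data.frame(sample = character(), contig = character(),
                    seq = character(), chrom = character(),
                    pos = integer(), strand = character(),
                    up_len = integer(), down_len = integer(),
                    gap = integer(), stringsAsFactors = FALSE),
       unplaced = if (length(unplaced)) do.call(rbind, unplaced) else
         data.frame(sample = character(), contig = character(),
                    seq = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Filter unplaced sequences
#'
#' Applies, independently, the four unplaced-sequence filters: whole
#' sequence realigns to the reference at identity >= 0.90 with coverage
#' >= 0.80 (`genome_hit`); tandem-repeat masked fraction > 0.80
#' (`trf80`); combined satellite + simple-repeat + low-complexity masked
#' fraction > 0.80 (`repeat80`); and cross-sample singleton occurrence
#' (`singleton`, using the merging-stage match criteria).  Retained
#' sequences carry no flag.  The operation is idempotent.
#'
#' @param unplaced unplaced data frame (`sample`, `seq`, ...).
#' @param reference reference object or index.
#' @param satellite_library monomer library.
#' @return `unplaced` with logical flag columns and `retained`.
#' @export
filter_unplaced <- function(unplaced, reference,
                            satellite_library = satellite_library()) {
  index <- if (inherits(reference, "nrs_target_index")) reference else
    build_target_index(reference)
  n <- nrow(unplaced)
  gh <- logical(n); t8 <- logical(n); r8 <- logical(n)
  for (i in seq_len(n)) {
    s <- unplaced$seq[i]
    aln <- align_pair(s, index, mode = "glocal")
    gh[i] <- nrow(aln) > 0 && any(aln$identity >= 0.90 &
                                    aln$coverage >= 0.80)
    tr <- scan_tandem_repeats(s)
    t8[i] <- mask_and_fraction(s, tr)$fraction > 0.80
    sat <- match_satellites(s, satellite_library)
    lc <- scan_low_complexity(s)
    r8[i] <- mask_and_fraction(s, rbind(tr, sat, lc))$fraction > 0.80
  }
  comp <- unplaced_components(unplaced$seq, unplaced$sample)
  sg <- comp$n_individuals[as.character(comp$component)] == 1L
  unplaced$flag_genome_hit <- gh
  unplaced$flag_trf80 <- t8
  unplaced$flag_repeat80 <- r8
  unplaced$flag_singleton <- sg
  unplaced$retained <- !(gh | t8 | r8 | sg)
  unplaced
}

#' Permutation-based insertion hotspot scan
#'
#' Gaussian kernel density of insertion points per chromosome at
#' bandwidth `bw`, compared against `trials` draws of the same number of
#' points uniform over the non-gap (non-satellite) genome.  Maximal
#' regions where the observed density exceeds the null's pointwise 95th
#' percentile, and which contain at least two insertion points, are
#' reported with the empirical p-value
#' `(1 + #trials with global peak >= observed region peak) / (trials+1)`.
#'
#' @param placed placed-call data frame (`chrom`, `pos`).
#' @param reference reference object (chromosome lengths + satellite
#'   track to exclude from the null).
#' @param bw kernel bandwidth in bp (default 200000).
#' @param trials number of null draws (default 1000; < 100 warns).
#' @param seed RNG seed for the null draws.
#' @param grid_n density grid points per chromosome.
#' @return data frame (chrom, start, end, n_points, peak, p).
#' @export
hotspot_scan <- function(placed, reference, bw = 200000, trials = 1000L,
                         seed = 1L, grid_n = 512L) {
  if (nrow(placed) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_points = integer(),
                      peak = numeric(), p = numeric()))
  if (trials < 100L) warning("fewer than 100 permutation trials")
  out <- list()
  with_substream(seed, "hotspots", {
    for (chrom in unique(placed$chrom)) {
      pos <- placed$pos[placed$chrom == chrom]
      L <- reference$chrom_lengths[[chrom]]
      sat <- reference$satellites[reference$satellites$chrom == chrom, ,
                                  drop = FALSE]
      allowed <- setdiff(seq(0L, L - 1L, by = 1000L), unlist(lapply(
        seq_len(nrow(sat)),
        function(i) seq(sat$start[i], sat$end[i], by = 1000L))))
      dens <- function(x) density(x, bw = bw, from = 0, to = L,
                                  n = grid_n)$y * length(x)
      obs <- dens(pos)
      null <- matrix(0, trials, grid_n)
      peaks <- numeric(trials)
      for (t in seq_len(trials)) {
        x <- sample(allowed, length(pos), replace = TRUE) +
          runif(length(pos), 0, 1000)
        d <- dens(x)
        null[t, ] <- d
        peaks[t] <- max(d)
      }
      thr <- apply(null, 2L, quantile, probs = 0.95)
      exceed <- obs > thr
      if (!any(exceed)) next
      r <- rle(exceed)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      gx <- seq(0, L, length.out = grid_n)
      for (j in which(r$values)) {
        a <- gx[starts[j]]; b <- gx[ends[j]]
        npt <- sum(pos >= a - bw & pos <= b + bw)
        if (npt < 2L) next
        pk <- max(obs[starts[j]:ends[j]])
        p <- (1 + sum(peaks >= pk)) / (trials + 1)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = as.integer(a), end = as.integer(b),
          n_points = npt, peak = pk, p = p, stringsAsFactors = FALSE)
      }
    }
  })
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_points = integer(),
                      peak = numeric(), p = numeric()))
  do.call(rbind, out)
}

#' Chromosome arm-end enrichment of insertions
#'
#' Tests whether placed insertions are enriched in the distal `window`
#' bp of chromosome arms.  The 2x2 table compares observed counts inside
#' and outside the windows with counts expected from the genome-length
#' share of the windows; significance via Fisher's exact test.
#'
#' @param placed placed-call data frame (`chrom`, `pos`).
#' @param reference reference object with an `arms` table.
#' @param window distal window size in bp per arm (default 5 Mb).
#' @return list (odds_ratio, p, table, all_inside flag).
#' @export
arm_end_enrichment <- function(placed, reference, window = 5000000) {
  if (nrow(placed) == 0L) stop("no placed insertions")
  arms <- reference$arms
  win <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    w <- min(window, a$end - a$start)
    if (a$arm == "p") data.frame(chrom = a$chrom, start = a$start,
                                 end = a$start + w)
    else data.frame(chrom = a$chrom, start = a$end - w, end = a$end)
  }))
  inside <- vapply(seq_len(nrow(placed)), function(i) {
    any(win$chrom == placed$chrom[i] & placed$pos[i] >= win$start &
          placed$pos[i] < win$end)
  }, logical(1))
  n_in <- sum(inside); n_out <- sum(!inside)
  bp_in <- sum(win$end - win$start)
  bp_total <- sum(reference$chrom_lengths)
  e_in <- round(nrow(placed) * bp_in / bp_total)
  e_out <- nrow(placed) - e_in
  if (n_out == 0L)
    return(list(odds_ratio = Inf, p = NA_real_,
                table = matrix(c(n_in, n_out, e_in, e_out), 2),
                all_inside = TRUE))
  tab <- matrix(c(n_in, n_out, e_in, e_out), nrow = 2,
                dimnames = list(c("inside", "outside"),
                                c("observed", "expected")))
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab,
       all_inside = FALSE)
}
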