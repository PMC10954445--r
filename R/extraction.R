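#' Extract unaligned segments from contigs
#'
#' Stage 1 of the pipeline.  Contigs shorter than `min_contig` are
#' skipped; each remaining contig is aligned to the reference and the
#' parts of the contig not covered by any kept alignment (identity >=
#' `keep_identity`, aligned length >= `keep_length`) and at least
#' `min_segment` bp long are emitted as raw segments -- both fully
#' unaligned contigs and internal unaligned fragments.
#'
#' @param contigs named character vector of contig sequences.
#' @param reference reference object / sequences / prebuilt index.
#' @param depth optional per-contig depth track (data frame with `contig`,
#'   `depth`); joined onto segments.
#' @param min_contig minimum contig length considered (default 1000).
#' @param min_segment minimum emitted segment length (default 50; the
#'   conventional insertion-SV floor).
#' @param keep_identity,keep_length what counts as a real alignment.
#' @param sample sample id recorded on the segments.
#' @return data frame of raw segments (`sample`, `contig`, `start`,
#'   `end`, `length`, `seq`, `depth`, logical filter-flag columns
#'   `flag_depth`, `flag_satellite`, `flag_contaminant`), with the contig
#'   alignments attached as attribute `"alignments"` for reuse.
#' @export
extract_unaligned <- function(contigs, reference, depth = NULL,
                              min_contig = 1000L, min_segment = 50L,
                              keep_identity = 0.8, keep_length = 100L,
                              sample = "sample") {
  index <- if (inherits(reference, "nrs_target_index")) reference else
    build_target_index(reference)
  bad <- grepl("[^ACGTN]", toupper(contigs))
  if (any(bad))
    stop("contig with non-ACGTN characters: ",
         paste(names(contigs)[bad], collapse = ", "))
  segs <- list(); alns <- list()
  for (cid in names(contigs)) {
    cseq <- toupper(contigs[[cid]])
    n <- nchar(cseq)
    if (n < min_contig) next
    aln <- align_pair(cseq, index, mode = "glocal", both_strands = TRUE,
                      min_seeds = 3L, method = "chain",
                      max_candidates = 64L)
    if (nrow(aln) > 0L) aln$query_id <- cid
    keep <- aln[aln$identity >= keep_identity & aln$aln_len >= keep_length, ,
                drop = FALSE]
    alns[[cid]] <- keep
    covered <- logical(n)
    for (i in seq_len(nrow(keep))) {
      a <- max(1L, keep$qstart[i] + 1L); b <- min(n, keep$qend[i])
      if (b >= a) covered[a:b] <- TRUE
    }
    r <- rle(!covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_segment)) {
      s0 <- starts[j] - 1L; s1 <- ends[j]
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sample, contig = cid, start = s0, end = s1,
        length = s1 - s0, seq = substr(cseq, s0 + 1L, s1),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(), contig = character(),
               start = integer(), end = integer(), length = integer(),
               seq = character(), stringsAsFactors = FALSE)
  out$segment_id <- sprintf("%s_seg%04d", sample, seq_len(nrow(out)))
  out$depth <- if (!is.null(depth))
    depth$depth[match(out$contig, depth$contig)] else
    rep(NA_real_, nrow(out))
  out$flag_depth <- rep(FALSE, nrow(out))
  out$flag_satellite <- rep(FALSE, nrow(out))
  out$flag_contaminant <- rep(FALSE, nrow(out))
  attr(out, "alignments") <- if (length(alns)) do.call(rbind, alns) else
    empty_alignments()
  out
}

#' Depth filter
#'
#' Flags segments whose depth exceeds 3x or falls below 1/3 of the
#' sample's mean depth.  Flagged segments are excluded downstream.
#'
#' @param segments raw-segment data frame.
#' @param mean_depth the sample's mean depth (> 0); if missing it is the
#'   mean of the segments' contig depths.
#' @return segments with `flag_depth` set.
#' @export
depth_filter <- function(segments, mean_depth = NULL) {
  if (all(is.na(segments$depth))) {
    warning("no depth track; depth filter passed through")
    segments$flag_depth <- FALSE
    return(segments)
  }
  if (is.null(mean_depth)) mean_depth <- mean(segments$depth, na.rm = TRUE)
  stopifnot(mean_depth > 0)
  d <- segments$depth
  segments$flag_depth <- !is.na(d) &
    (d > 3 * mean_depth | d < mean_depth / 3)
  segments
}

#' Satellite filter
#'
#' Flags segments whose satellite-masked fraction is at least
#' `threshold` (default 0.80; the boundary value is flagged).
#'
#' @param segments raw-segment data frame.
#' @param satellite_library monomer library (see [satellite_library()]).
#' @param threshold masked-fraction cutoff.
#' @return segments with `flag_satellite` set.
#' @export
satellite_filter <- function(segments, satellite_library,
                             threshold = 0.80) {
  lk <- satellite_kmer_sets(satellite_library)
  segments$flag_satellite <- vapply(segments$seq, function(s) {
    ann <- match_satellites(s, satellite_library, lib_kmers = lk)
    mask_and_fraction(s, ann)$fraction >= threshold
  }, logical(1), USE.NAMES = FALSE)
  segments
}

#' Contamination filter
#'
#' Each segment is repeat-masked and classified by composition (primary
#' classifier).  Segments labelled `non_chordate` are re-queried by the
#' secondary classifier: alignment of the unmasked segment to the host
#' reference; an alignment with identity >= `rescue_identity` and
#' coverage >= `rescue_coverage` rescues the segment.  The contaminant
#' flag is set only when both classifiers agree on `non_chordate`;
#' `unclassified` segments are kept.
#'
#' @param segments raw-segment data frame.
#' @param host_profile,foreign_profiles composition profiles.
#' @param reference host reference (index) for the rescue alignment.
#' @param rescue_identity,rescue_coverage rescue-alignment thresholds.
#' @return segments with `flag_contaminant` set.
#' @export
contamination_filter <- function(segments, host_profile, foreign_profiles,
                                 reference, rescue_identity = 0.9,
                                 rescue_coverage = 0.8) {
  index <- if (inherits(reference, "nrs_target_index")) reference else
    build_target_index(reference)
  segments$flag_contaminant <- vapply(segments$seq, function(s) {
    # below the classifier window the label is always "unclassified",
    # which is kept -- skip the masking work entirely
    if (nchar(s) < 300L) return(FALSE)
    tr <- scan_tandem_repeats(s)
    lc <- scan_low_complexity(s)
    masked <- mask_and_fraction(s, rbind(tr, lc))$masked
    lab <- classify_taxon(masked, host_profile, foreign_profiles)
    if (lab$value != "non_chordate") return(FALSE)
    aln <- align_pair(s, index, mode = "glocal")
    rescued <- nrow(aln) > 0 &&
      any(aln$identity >= rescue_identity &
            aln$coverage >= rescue_coverage)
    !rescued
  }, logical(1), USE.NAMES = FALSE)
  segments
}

#' Segments surviving all filters
#'
#' @param segments filtered raw-segment data frame.
#' @return subset with no filter flag set.
#' @export
segments_pass <- function(segments) {
  segments[!segments$flag_depth & !segments$flag_satellite &
             !segments$flag_contaminant, , drop = FALSE]
}
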