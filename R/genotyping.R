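#' Genotype one sample against the catalogue
#'
#' Presence/absence genotyping of placed catalogue records from breakpoint
#' evidence, standing in for a graph genotyper behind the same contract.
#' For each placed record, contig-to-reference alignments spanning the
#' insertion point are inspected: a contig whose alignment is split
#' around the point with a query-side gap matching the record sequence
#' (identity >= 0.9, coverage >= 0.8) contributes insertion-allele
#' evidence; a contig aligned straight through the point contributes
#' reference-allele evidence.  Calls: alt only -> 1/1, both -> 0/1, ref
#' only -> 0/0; total evidence below `min_support` -> ./. (missing).
#' When `truth` is given (noise-free mode) evidence comes directly from
#' the sample's two simulated haplotypes.
#'
#' @param contigs the sample's contigs (named character), or NULL in
#'   truth mode.
#' @param catalogue `nrs_catalogue`.
#' @param reference reference object or index.
#' @param min_support minimum total evidence for a call (default 2, the
#'   two-read validation rule).
#' @param alignments optional precomputed contig alignments (from
#'   [extract_unaligned()]); computed when missing.
#' @param truth,sample truth-mode inputs: an `nrs_truth` object and the
#'   sample id.
#' @param margin breakpoint matching slack in bp (default 100).
#' @return list with `geno` (character vector per record: "0/0", "0/1",
#'   "1/1", "./.") and `support` (alt/ref evidence counts).
#' @export
genotype_sample <- function(contigs, catalogue, reference,
                            min_support = 2L, alignments = NULL,
                            truth = NULL, sample = NULL, margin = 100L) {
  placed <- which(catalogue$placed)
  geno <- rep("./.", nrow(catalogue))
  names(geno) <- catalogue$gnrs_id
  alt_n <- integer(nrow(catalogue)); ref_n <- integer(nrow(catalogue))
  if (!is.null(truth)) {
    stopifnot(!is.null(sample))
    ev <- truth$events
    for (i in placed) {
      if (!catalogue$chrom[i] %in% ev$chrom)
        stop("record chromosome absent from truth: ", catalogue$chrom[i])
      j <- which(ev$chrom == catalogue$chrom[i] &
                   abs(ev$pos - catalogue$pos[i]) <= margin)
      carried <- if (length(j) > 0L)
        truth$presence[j[1], sample, ] else c(FALSE, FALSE)
      alt_n[i] <- sum(carried); ref_n[i] <- 2L - sum(carried)
    }
  } else {
    index <- if (inherits(reference, "nrs_target_index")) reference else
      build_target_index(reference)
    if (!all(stats::na.omit(unique(catalogue$chrom)) %in%
               names(index$seqs)))
      stop("record chromosome absent from reference")
    if (is.null(alignments)) {
      segs <- extract_unaligned(contigs, index,
                                sample = sample %||% "sample")
      alignments <- attr(segs, "alignments")
    }
    aln <- alignments
    for (i in placed) {
      ch <- catalogue$chrom[i]; p <- catalogue$pos[i]
      rl <- catalogue$length[i]
      a <- aln[aln$target_id == ch & aln$tstart < p + margin &
                 aln$tend > p - margin, , drop = FALSE]
      for (cid in unique(a$query_id)) {
        ca <- a[a$query_id == cid, , drop = FALSE]
        full <- aln[aln$query_id == cid & aln$target_id == ch, ,
                    drop = FALSE]
        # insertion evidence: two blocks abutting the point whose
        # query-side gap holds the record sequence
        got_alt <- FALSE
        if (nrow(full) >= 2L) {
          full <- full[order(full$tstart), , drop = FALSE]
          for (b in seq_len(nrow(full) - 1L)) {
            tgap <- full$tstart[b + 1L] - full$tend[b]
            lo <- min(full$qend[b], full$qstart[b + 1L])
            hi <- max(full$qend[b], full$qstart[b + 1L])
            qgap <- hi - lo
            near <- abs(full$tend[b] - p) <= margin ||
              abs(full$tstart[b + 1L] - p) <= margin
            if (!near || tgap > margin || qgap < 0.5 * rl) next
            gseq <- substr(contigs[[cid]], lo + 1L, hi)
            # direct DP: seeded alignment is blind to tandem-repeat
            # records whose k-mers are multiplicity-capped
            chk <- seq_similarity(catalogue$seq[i], gseq)
            if (chk$identity >= 0.9 && chk$coverage >= 0.8) {
              got_alt <- TRUE; break
            }
          }
        }
        if (got_alt) alt_n[i] <- alt_n[i] + 1L
        else if (any(ca$tstart <= p - margin & ca$tend >= p + margin))
          ref_n[i] <- ref_n[i] + 1L
      }
    }
  }
  for (i in placed) {
    tot <- alt_n[i] + ref_n[i]
    geno[i] <- if (tot < min_support) "./."
      else if (alt_n[i] > 0L && ref_n[i] == 0L) "1/1"
      else if (alt_n[i] > 0L) "0/1" else "0/0"
  }
  list(geno = geno, support = data.frame(gnrs_id = catalogue$gnrs_id,
                                         alt = alt_n, ref = ref_n))
}

#' Dosage matrix from genotype strings
#'
#' @param geno character matrix (loci x samples) of "0/0", "0/1", "1/1",
#'   "./.".
#' @return integer matrix of 0/1/2 with NA for missing.
#' @export
geno_to_dosage <- function(geno) {
  d <- matrix(NA_integer_, nrow(geno), ncol(geno),
              dimnames = dimnames(geno))
  d[geno == "0/0"] <- 0L; d[geno == "0/1"] <- 1L; d[geno == "1/1"] <- 2L
  d
}

#' Trio Mendelian error rate
#'
#' A (locus, trio) pair is an error when the child genotype is impossible
#' under biallelic transmission given the parents; pairs with any missing
#' genotype are excluded.
#'
#' @param dosage loci x samples dosage matrix (NA = missing).
#' @param trios data frame (`child`, `father`, `mother`).
#' @return list (`rate`, `n_errors`, `n_evaluated`, per-trio table).
#' @export
mendelian_error_rate <- function(dosage, trios) {
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  per <- lapply(seq_len(nrow(trios)), function(t) {
    f <- dosage[, trios$father[t]]; m <- dosage[, trios$mother[t]]
    ch <- dosage[, trios$child[t]]
    ok <- !is.na(f) & !is.na(m) & !is.na(ch)
    err <- vapply(which(ok), function(i) {
      poss <- outer(transmit[[as.character(f[i])]],
                    transmit[[as.character(m[i])]], `+`)
      !(ch[i] %in% poss)
    }, logical(1))
    data.frame(trio = trios$child[t], n_evaluated = sum(ok),
               n_errors = sum(err), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  n_ev <- sum(tab$n_evaluated); n_er <- sum(tab$n_errors)
  list(rate = if (n_ev > 0L) n_er / n_ev else NA_real_,
       n_errors = n_er, n_evaluated = n_ev, per_trio = tab)
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test of the heterozygote count given the allele
#' counts: the null distribution over all possible heterozygote counts
#' (same parity as the minor allele count) is enumerated and the p-value
#' sums the probabilities of configurations no more probable than the
#' observed one.
#'
#' @param hom_ref,het,hom_alt genotype counts.
#' @return the exact p-value (monomorphic data give p = 1).
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  if (n == 0L) return(1)
  na <- 2L * hom_alt + het          # alt allele count
  nr <- 2L * n - na
  nm <- min(na, nr)                 # minor allele count
  if (nm == 0L) return(1)
  hets <- seq(nm %% 2L, nm, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_min <- (nm - h) %/% 2L
    hom_maj <- n - h - hom_min
    # multinomial kernel; terms constant in h cancel after normalisation
    h * log(2) - lgamma(hom_min + 1) - lgamma(h + 1) -
      lgamma(hom_maj + 1)
  }, numeric(1))
  # normalise within the conditional distribution
  m <- max(logp)
  pr <- exp(logp - m); pr <- pr / sum(pr)
  obs <- pr[match(het, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Genotype concordance against truth
#'
#' Allele-presence sensitivity (true carriers called carrier / true
#' carriers among non-missing calls) and precision (true carriers among
#' called carriers).
#'
#' @param dosage called dosage matrix (NA = missing).
#' @param truth_dosage truth dosage matrix with matching dimnames.
#' @return list (sensitivity, precision, table).
#' @export
genotype_concordance <- function(dosage, truth_dosage) {
  truth_dosage <- truth_dosage[rownames(dosage), colnames(dosage),
                               drop = FALSE]
  called <- !is.na(dosage)
  carrier_call <- called & dosage > 0L
  carrier_true <- truth_dosage > 0L
  tp <- sum(carrier_call & carrier_true)
  sens <- tp / sum(carrier_true & called)
  prec <- tp / sum(carrier_call)
  list(sensitivity = sens, precision = prec,
       table = table(called = as.vector(carrier_call),
                     truth = as.vector(carrier_true)))
}
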