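#' PCA on the genotype matrix
#'
#' Loci are filtered on minor allele frequency and Hardy-Weinberg
#' equilibrium, dosages are centred at 2p and scaled by sqrt(2p(1-p)),
#' and sample scores come from the singular value decomposition.  Sign
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param dosage loci x samples dosage matrix (NA imputed at the locus
#'   mean).
#' @param maf_min MAF filter (strictly greater; default 0.05).
#' @param hwe_p_min HWE exact-test p-value floor (default 1e-4).
#' @param n_components number of components returned.
#' @return list (`scores` samples x PCs, `explained` variance fractions,
#'   `loci` ids used).
#' @export
genotype_pca <- function(dosage, maf_min = 0.05, hwe_p_min = 0.0001,
                         n_components = 2L) {
  p <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(nrow(dosage)), function(i) {
    d <- dosage[i, ]
    hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                   sum(d == 2L, na.rm = TRUE))
  }, numeric(1))
  keep <- which(maf > maf_min & hwe >= hwe_p_min)
  if (length(keep) == 0L) stop("no locus passes the PCA filters")
  X <- dosage[keep, , drop = FALSE]
  pk <- p[keep]
  for (i in seq_len(nrow(X))) X[i, is.na(X[i, ])] <- 2 * pk[i]
  Z <- (X - 2 * pk) / sqrt(2 * pk * (1 - pk))
  if (all(abs(Z) < 1e-12)) stop("genotypes carry no variance")
  sv <- svd(t(Z), nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (j in seq_len(ncol(scores))) {
    v <- sv$u[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(dosage)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       loci = rownames(dosage)[keep])
}

#' Hudson's FST estimator
#'
#' Per locus: `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `D = p1(1-p2) + p2(1-p1)`, `FST = N/D` (NA when D = 0).
#'
#' @param ac1,an1 alt allele count and allele number in population 1.
#' @param ac2,an2 same for population 2.
#' @return numeric vector of per-locus FST.
#' @export
hudson_fst <- function(ac1, an1, ac2, an2) {
  p1 <- ac1 / an1; p2 <- ac2 / an2
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(D == 0, NA_real_, N / D)
}

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` with `T = -log(1 - FST)`; FST
#' values are clamped to `[0, 1 - 1e-9]` first.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST values (vectors allowed).
#' @return PBS for the focal population A.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  cl <- function(x) pmin(pmax(x, 0), 1 - 1e-9)
  tt <- function(x) -log(1 - cl(x))
  (tt(fst_ab) + tt(fst_ac) - tt(fst_bc)) / 2
}

pop_allele_counts <- function(dosage, panel, population, samples = NULL) {
  smp <- samples %||% panel$sample[panel$population == population]
  smp <- intersect(smp, colnames(dosage))
  d <- dosage[, smp, drop = FALSE]
  list(ac = rowSums(d, na.rm = TRUE), an = 2 * rowSums(!is.na(d)))
}

#' PBS selection scan with downsampling consensus
#'
#' The focal population is downsampled (without replacement) to
#' `downsample_to` samples, `replicates` times; per replicate, per-locus
#' PBS is computed from Hudson FST and loci in the top `top_quantile`
#' are tallied.  Candidates are loci hit in at least `consensus_min`
#' replicates whose batch-effect q-value is at least 0.05; candidates
#' within `merge_window` bp chain into one signal, represented by the
#' locus with the highest mean PBS.
#'
#' @param dosage loci x samples dosage matrix.
#' @param loci data frame (`gnrs_id`, `chrom`, `pos`) aligned to rows.
#' @param panel panel data frame (population, platform).
#' @param focal,sister,outgroup population labels (PBS focal = `focal`).
#' @param maf_min combined-MAF filter (default 0.01).
#' @param downsample_to,replicates,top_quantile,consensus_min consensus
#'   parameters (defaults 40 / 10 / 0.001 / 7).
#' @param merge_window signal-merging window (default 1 Mb).
#' @param seed RNG seed for the downsampling.
#' @return list with `results` (per-locus table) and `signals`.
#' @export
pbs_scan <- function(dosage, loci, panel, focal, sister, outgroup,
                     maf_min = 0.01, downsample_to = 40L,
                     replicates = 10L, top_quantile = 0.001,
                     consensus_min = 7L, merge_window = 1000000L,
                     seed = 1L) {
  pops <- c(focal, sister, outgroup)
  insc <- panel$sample[panel$population %in% pops &
                         !(panel$trio_role %in% "offspring")]
  d <- dosage[, intersect(colnames(dosage), insc), drop = FALSE]
  af_all <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af_all, 1 - af_all)
  poly <- maf >= maf_min & !is.na(maf)
  focal_all <- intersect(panel$sample[panel$population == focal],
                         colnames(d))
  pbs_mat <- matrix(NA_real_, nrow(d), replicates)
  hit <- matrix(FALSE, nrow(d), replicates)
  with_substream(seed, "pbs_scan", {
    for (r in seq_len(replicates)) {
      smp_f <- if (length(focal_all) > downsample_to)
        sample(focal_all, downsample_to) else focal_all
      a <- pop_allele_counts(d, panel, focal, samples = smp_f)
      b <- pop_allele_counts(d, panel, sister)
      c_ <- pop_allele_counts(d, panel, outgroup)
      v <- pbs(hudson_fst(a$ac, a$an, b$ac, b$an),
               hudson_fst(a$ac, a$an, c_$ac, c_$an),
               hudson_fst(b$ac, b$an, c_$ac, c_$an))
      v[!poly] <- NA_real_
      pbs_mat[, r] <- v
      thr <- quantile(v, 1 - top_quantile, na.rm = TRUE)
      hit[, r] <- !is.na(v) & v >= thr
    }
  })
  nhit <- rowSums(hit)
  batch <- batch_effect_filter(d, panel)
  res <- data.frame(gnrs_id = loci$gnrs_id, chrom = loci$chrom,
                    pos = loci$pos, mean_pbs = rowMeans(pbs_mat),
                    n_hits = nhit, batch_q = batch$q,
                    stringsAsFactors = FALSE)
  res$candidate <- res$n_hits >= consensus_min &
    (is.na(res$batch_q) | res$batch_q >= 0.05)
  cand <- res[res$candidate, , drop = FALSE]
  signals <- NULL
  if (nrow(cand) > 0L) {
    cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
    grp <- unlist(lapply(split(seq_len(nrow(cand)), cand$chrom),
                         function(ii) {
      cumsum(c(1L, diff(cand$pos[ii]) > merge_window))
    }))
    key <- paste(cand$chrom, grp)
    signals <- do.call(rbind, lapply(split(cand, key), function(s) {
      s[which.max(s$mean_pbs), c("gnrs_id", "chrom", "pos", "mean_pbs"),
        drop = FALSE]
    }))
    signals$n_loci <- as.vector(table(key)[order(names(table(key)))])
    rownames(signals) <- NULL
  }
  list(results = res, signals = signals)
}

#' Platform batch-effect filter
#'
#' Per locus, within every population sampled on more than one platform,
#' a chi-squared test of genotype class against platform; the minimum p
#' across populations is Benjamini-Hochberg corrected across loci.  Loci
#' with q < 0.05 are considered batch-affected.
#'
#' @param dosage loci x samples dosage matrix.
#' @param panel panel data frame (`sample`, `population`, `platform`).
#' @return data frame (p, q) per locus; NA when no population is
#'   multi-platform.
#' @export
batch_effect_filter <- function(dosage, panel) {
  pops <- unique(panel$population[panel$sample %in% colnames(dosage)])
  pmat <- matrix(NA_real_, nrow(dosage), length(pops))
  for (pi in seq_along(pops)) {
    smp <- intersect(panel$sample[panel$population == pops[pi]],
                     colnames(dosage))
    plat <- panel$platform[match(smp, panel$sample)]
    if (length(unique(plat)) < 2L) next
    d <- dosage[, smp, drop = FALSE]
    pmat[, pi] <- vapply(seq_len(nrow(d)), function(i) {
      g <- factor(d[i, ], levels = 0:2)
      tab <- table(g, plat)
      tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
      if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }, numeric(1))
  }
  p <- suppressWarnings(apply(pmat, 1L, min, na.rm = TRUE))
  p[!is.finite(p)] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  data.frame(p = p, q = q)
}
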