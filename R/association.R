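#' Fast covariate-adjusted linear association
#'
#' Residualises the response and every locus on the covariates (with
#' intercept), then computes the dosage coefficient, its standard error
#' and the Wald p-value in closed form.  Equivalent to per-locus
#' `lm(y ~ g + covariates)` (verified in the test suite).
#'
#' @param y response vector (length n).
#' @param G loci x samples dosage matrix (NA imputed at locus means).
#' @param C optional n x k covariate matrix.
#' @return data frame (beta, se, t, p, df).
#' @export
assoc_linear <- function(y, G, C = NULL) {
  n <- length(y)
  X <- cbind(rep(1, n), C)
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  Gi <- G
  for (i in seq_len(nrow(Gi)))
    if (anyNA(Gi[i, ])) Gi[i, is.na(Gi[i, ])] <- mean(Gi[i, ], na.rm = TRUE)
  RG <- t(qr.resid(qx, t(Gi)))
  gg <- rowSums(RG^2)
  gy <- as.vector(RG %*% ry)
  beta <- ifelse(gg > 0, gy / gg, NA_real_)
  df <- n - ncol(X) - 1L
  rss <- sum(ry^2) - ifelse(gg > 0, beta^2 * gg, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(beta = beta, se = se, t = tval, p = p, df = df)
}

#' cis-eQTL scan
#'
#' For every transcript, every passing locus within `window` bp of the
#' TSS is tested with the linear model expression ~ dosage + covariates;
#' p-values are Benjamini-Hochberg corrected across all tested pairs.
#' Loci are filtered on MAF and (optionally) multi-allelic status.
#'
#' @param expr transcripts x samples expression matrix.
#' @param dosage loci x samples dosage matrix.
#' @param tss data frame (`gene_id`, `chrom`, `tss`).
#' @param loci data frame (`gnrs_id`, `chrom`, `pos`) aligned to dosage
#'   rows; may carry `multi_allelic`.
#' @param window cis window around the TSS (default 1 Mb).
#' @param maf_min MAF filter (strictly greater; default 0.05).
#' @param drop_multiallelic drop flagged loci (default TRUE).
#' @param covariates n x k matrix, or NULL to use `n_pcs` genotype PCs.
#' @param n_pcs genotype PCs used when `covariates` is NULL (default 5).
#' @param fdr FDR level for the significance flag (default 0.05).
#' @return data frame of tested pairs (locus, transcript, beta, se, p,
#'   q, significant).
#' @export
cis_eqtl_scan <- function(expr, dosage, tss, loci, window = 1000000L,
                          maf_min = 0.05, drop_multiallelic = TRUE,
                          covariates = NULL, n_pcs = 5L, fdr = 0.05) {
  common <- intersect(colnames(expr), colnames(dosage))
  expr <- expr[, common, drop = FALSE]
  dosage <- dosage[, common, drop = FALSE]
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > maf_min & !is.na(maf)
  if (drop_multiallelic && !is.null(loci$multi_allelic))
    keep <- keep & !loci$multi_allelic
  if (is.null(covariates)) {
    npc <- min(n_pcs, length(common) - 2L)
    pca <- genotype_pca(dosage, maf_min = maf_min,
                        n_components = npc)
    covariates <- pca$scores
  }
  rows <- list()
  for (ti in seq_len(nrow(tss))) {
    cand <- which(keep & loci$chrom == tss$chrom[ti] &
                    abs(loci$pos - tss$tss[ti]) <= window)
    if (length(cand) == 0L) next
    a <- assoc_linear(expr[tss$gene_id[ti], ],
                      dosage[cand, , drop = FALSE], covariates)
    rows[[length(rows) + 1L]] <- data.frame(
      gnrs_id = loci$gnrs_id[cand], transcript = tss$gene_id[ti],
      beta = a$beta, se = a$se, p = a$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gnrs_id = character(), transcript = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  bh <- bh_fdr(out$p, fdr)
  out$q <- bh$q
  out$significant <- bh$significant
  out
}

#' Genome-wide association of catalogue genotypes with traits
#'
#' Additive model per locus: linear regression for quantitative traits,
#' logistic for binary.  Covariates default to age, sex, BMI and the
#' first two genotype PCs; BMI is dropped from the covariates when it is
#' itself the tested trait.  Reports the genomic inflation factor
#' (median Wald chi-squared / 0.4549) and the Bonferroni threshold.
#'
#' @param dosage loci x samples dosage matrix.
#' @param phenotypes data frame with `sample`, covariate columns and one
#'   column per trait.
#' @param traits named character vector: trait -> "quantitative" or
#'   "binary".
#' @param covariate_cols covariate column names (default age, sex, bmi).
#' @param pc_scores optional samples x PC matrix appended to covariates.
#' @param maf_min MAF filter (default 0.05).
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @return list with `results` (per trait x locus), `lambda_gc` (per
#'   trait), `threshold`, `m` (loci tested).
#' @export
gwas <- function(dosage, phenotypes, traits,
                 covariate_cols = c("age", "sex", "bmi"),
                 pc_scores = NULL, maf_min = 0.05, alpha = 0.05) {
  samples <- intersect(phenotypes$sample, colnames(dosage))
  ph <- phenotypes[match(samples, phenotypes$sample), , drop = FALSE]
  d <- dosage[, samples, drop = FALSE]
  af <- rowMeans(d, na.rm = TRUE) / 2
  keep <- pmin(af, 1 - af) > maf_min & !is.na(af)
  d <- d[keep, , drop = FALSE]
  m <- nrow(d)
  thr <- bonferroni_threshold(alpha, m)
  results <- list(); lambda <- setNames(numeric(0), character(0))
  for (tr in names(traits)) {
    cov_cols <- setdiff(covariate_cols, if (tolower(tr) == "bmi")
      tolower(tr) else character(0))
    cov_cols <- setdiff(cov_cols, tr)
    C <- as.matrix(ph[, cov_cols, drop = FALSE])
    if (!is.null(pc_scores)) C <- cbind(C, pc_scores[samples, ,
                                                     drop = FALSE])
    y <- ph[[tr]]
    if (traits[[tr]] == "quantitative") {
      a <- assoc_linear(y, d, C)
      res <- data.frame(trait = tr, gnrs_id = rownames(d),
                        beta = a$beta, se = a$se, p = a$p,
                        stringsAsFactors = FALSE)
    } else {
      res <- do.call(rbind, lapply(seq_len(m), function(i) {
        g <- d[i, ]
        if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
        fit <- suppressWarnings(
          stats::glm(y ~ g + C, family = stats::binomial()))
        co <- summary(fit)$coefficients
        if (!"g" %in% rownames(co))
          return(data.frame(trait = tr, gnrs_id = rownames(d)[i],
                            beta = NA_real_, se = NA_real_, p = NA_real_,
                            stringsAsFactors = FALSE))
        data.frame(trait = tr, gnrs_id = rownames(d)[i],
                   beta = co["g", 1], se = co["g", 2], p = co["g", 4],
                   stringsAsFactors = FALSE)
      }))
    }
    chisq <- (res$beta / res$se)^2
    lambda[tr] <- median(chisq, na.rm = TRUE) / 0.4549
    res$significant <- !is.na(res$p) & res$p < thr$threshold
    results[[tr]] <- res
  }
  list(results = do.call(rbind, results), lambda_gc = lambda,
       threshold = thr, m = m)
}

#' Bonferroni threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return list (`threshold` = alpha/m, `display` rounded to 2
#'   significant figures).
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  t <- alpha / m
  list(threshold = t, display = signif(t, 2))
}

#' Squared dosage correlation (LD r-squared)
#'
#' @param a,b dosage vectors.
#' @param missing_policy `"as_ref"` codes missing genotypes as 0/0 (the
#'   catalogue-LD convention); `"pairwise"` drops incomplete pairs.
#' @return r-squared, or NA (with attribute `flag = "constant"`) when
#'   either vector is constant.
#' @export
ld_r2 <- function(a, b, missing_policy = c("as_ref", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  if (missing_policy == "as_ref") {
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  } else {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
  }
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_; attr(out, "flag") <- "constant"; return(out)
  }
  cor(a, b)^2
}

#' LD between catalogue records and phenotype-associated SNPs
#'
#' For each placed record, reports every SNP within `window` bp whose
#' catalogued association p-value is at most `snp_p_max` and whose
#' dosage r-squared with the record exceeds `r2_min`.
#'
#' @param dosage loci x samples NRS dosage matrix.
#' @param loci data frame (`gnrs_id`, `chrom`, `pos`).
#' @param snp_geno SNPs x samples dosage matrix.
#' @param snp_catalogue data frame (`snp_id`, `chrom`, `pos`, `p`).
#' @param window pairing window (default 100 kb).
#' @param r2_min LD threshold (strictly greater; default 0.8).
#' @param snp_p_max association significance cutoff (default 5e-8).
#' @param missing_policy passed to [ld_r2()] (default "as_ref").
#' @return data frame of (gnrs_id, snp_id, distance, r2, snp_p) pairs.
#' @export
ld_catalogue_scan <- function(dosage, loci, snp_geno, snp_catalogue,
                              window = 100000L, r2_min = 0.8,
                              snp_p_max = 5e-8,
                              missing_policy = "as_ref") {
  common <- intersect(colnames(dosage), colnames(snp_geno))
  out <- list()
  sig <- snp_catalogue[snp_catalogue$p <= snp_p_max, , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    if (is.na(loci$pos[i])) next
    cand <- sig[sig$chrom == loci$chrom[i] &
                  abs(sig$pos - loci$pos[i]) <= window, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      r2 <- ld_r2(dosage[i, common], snp_geno[cand$snp_id[j], common],
                  missing_policy)
      if (!is.na(r2) && r2 > r2_min)
        out[[length(out) + 1L]] <- data.frame(
          gnrs_id = loci$gnrs_id[i], snp_id = cand$snp_id[j],
          distance = abs(cand$pos[j] - loci$pos[i]), r2 = r2,
          snp_p = cand$p[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gnrs_id = character(), snp_id = character(),
                      distance = integer(), r2 = numeric(),
                      snp_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up
#'
#' @param p p-value vector.
#' @param q FDR level for the significance flags (default 0.05).
#' @return list (`q` monotone q-values, `significant` logical flags).
#' @export
bh_fdr <- function(p, q = 0.05) {
  qv <- p.adjust(p, method = "BH")
  list(q = qv, significant = !is.na(qv) & qv <= q)
}
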