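test_that("assoc_linear agrees with lm per locus", {
  set.seed(71)
  n <- 80L
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  G <- rbind(L1 = rbinom(n, 2L, 0.3), L2 = rbinom(n, 2L, 0.5))
  colnames(G) <- paste0("s", 1:n)
  y <- 0.5 * G[1, ] + 0.2 * C[, 1] + rnorm(n)
  a <- assoc_linear(y, G, C)
  for (i in 1:2) {
    fit <- summary(lm(y ~ G[i, ] + C))$coefficients
    expect_equal(a$beta[i], fit[2, 1], tolerance = 1e-10)
    expect_equal(a$se[i], fit[2, 2], tolerance = 1e-10)
    expect_equal(a$p[i], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("cis_eqtl_scan recovers planted pairs and respects the window", {
  set.seed(72)
  n <- 200L
  n_loci <- 60L
  d <- do.call(rbind, lapply(1:n_loci, function(i) rbinom(n, 2L, 0.4)))
  dimnames(d) <- list(paste0("L", 1:n_loci), paste0("s", 1:n))
  loci <- data.frame(gnrs_id = rownames(d), chrom = "chr1",
                     pos = seq_len(n_loci) * 10000L,
                     multi_allelic = FALSE, stringsAsFactors = FALSE)
  loci$pos[2] <- 1500000L   # 1.2 Mb beyond the only TSS at 300 kb
  tss <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    tss = c(300000L, 400000L), stringsAsFactors = FALSE)
  expr <- rbind(G1 = 10 + 1.5 * d["L5", ] + rnorm(n),
                G2 = rnorm(n, 10))
  colnames(expr) <- colnames(d)
  res <- cis_eqtl_scan(expr, d, tss, loci, covariates = NULL, n_pcs = 2L)
  expect_true(res$significant[res$gnrs_id == "L5" &
                                res$transcript == "G1"])
  expect_false(any(res$gnrs_id == "L2"))   # outside the 1 Mb window
  # multi-allelic loci are dropped when flagged
  loci2 <- loci; loci2$multi_allelic[5] <- TRUE
  res2 <- cis_eqtl_scan(expr, d, tss, loci2, covariates = NULL,
                        n_pcs = 2L)
  expect_false(any(res2$gnrs_id == "L5"))
})

test_that("cis-eQTL null calibration keeps the realized FDR at bay", {
  set.seed(73)
  n <- 120L; n_loci <- 40L; n_tr <- 40L
  any_hit <- 0L
  reps <- 15L
  for (r in seq_len(reps)) {
    d <- do.call(rbind, lapply(1:n_loci, function(i) rbinom(n, 2L, 0.4)))
    dimnames(d) <- list(paste0("L", 1:n_loci), paste0("s", 1:n))
    loci <- data.frame(gnrs_id = rownames(d), chrom = "chr1",
                       pos = seq_len(n_loci) * 20000L,
                       multi_allelic = FALSE, stringsAsFactors = FALSE)
    tss <- data.frame(gene_id = paste0("G", 1:n_tr), chrom = "chr1",
                      tss = seq_len(n_tr) * 20000L,
                      stringsAsFactors = FALSE)
    expr <- matrix(rnorm(n_tr * n, 10), n_tr,
                   dimnames = list(tss$gene_id, colnames(d)))
    res <- cis_eqtl_scan(expr, d, tss, loci, covariates = NULL,
                         n_pcs = 2L)
    any_hit <- any_hit + as.integer(any(res$significant))
  }
  # under the complete null, BH at 5% yields any rejection in at most
  # ~5% of panels (plus Monte-Carlo error)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(any_hit / reps, 0.05 + 2 * se + 1e-9)
})

test_that("gwas: null inflation, planted recovery, BMI exclusion", {
  set.seed(74)
  n <- 300L; m <- 5000L
  d <- matrix(rbinom(n * m, 2L, 0.3), m,
              dimnames = list(paste0("L", 1:m), paste0("s", 1:n)))
  ph <- data.frame(sample = colnames(d), age = rnorm(n, 50, 10),
                   sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 24, 3),
                   stringsAsFactors = FALSE)
  ph$GLU <- rnorm(n)
  g0 <- gwas(d, ph, traits = c(GLU = "quantitative"))
  expect_gt(unname(g0$lambda_gc["GLU"]), 0.95)
  expect_lt(unname(g0$lambda_gc["GLU"]), 1.05)
  expect_equal(g0$threshold$threshold, 0.05 / g0$m)

  # planted effect is recovered below the Bonferroni threshold
  ph$GLU2 <- 0.6 * d["L1", ] + rnorm(n)
  g1 <- gwas(d[1:500, ], ph, traits = c(GLU2 = "quantitative"))
  expect_true(g1$results$significant[g1$results$gnrs_id == "L1"])

  # BMI as the tested trait is excluded from its own covariates
  ph$bmi2 <- ph$bmi
  gb <- gwas(d[1:50, ], ph, traits = c(bmi = "quantitative"))
  expect_true(all(is.finite(gb$results$p)))

  # binary trait via logistic model
  ph$T2D <- rbinom(n, 1, plogis(0.8 * scale(d["L2", ])[, 1]))
  g2 <- gwas(d[1:40, ], ph, traits = c(T2D = "binary"))
  expect_lt(g2$results$p[g2$results$gnrs_id == "L2"], 1e-3)
})

test_that("family-wise error at the Bonferroni threshold is controlled", {
  set.seed(75)
  n <- 200L; m <- 2000L; reps <- 40L
  hits <- 0L
  for (r in seq_len(reps)) {
    d <- matrix(rbinom(n * m, 2L, 0.3), m,
                dimnames = list(paste0("L", 1:m), paste0("s", 1:n)))
    y <- rnorm(n)
    a <- assoc_linear(y, d)
    hits <- hits + as.integer(any(a$p < 0.05 / m, na.rm = TRUE))
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(hits / reps, 0.05 + 2 * se + 1e-9)
})

test_that("bonferroni_threshold display rounding", {
  b <- bonferroni_threshold(0.05, 5643)
  expect_equal(b$display, 8.9e-06)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 5)$threshold, 0.01)
})

test_that("ld_r2: identity, independence, missing policies, symmetry", {
  set.seed(76)
  a <- rbinom(500, 2L, 0.4)
  expect_equal(ld_r2(a, a), 1)
  low <- replicate(20, ld_r2(rbinom(500, 2L, 0.4), rbinom(500, 2L, 0.4)))
  expect_gte(mean(low < 0.05), 0.9)
  b <- rbinom(500, 2L, 0.4)
  expect_identical(ld_r2(a, b), ld_r2(b, a))
  const <- rep(1L, 500)
  r <- ld_r2(a, const)
  expect_true(is.na(r))
  expect_equal(attr(r, "flag"), "constant")
  # missing coded as 0/0 changes the estimate; pairwise deletion drops
  am <- a; am[1:100] <- NA
  expect_false(isTRUE(all.equal(ld_r2(am, b, "as_ref"),
                                ld_r2(am, b, "pairwise"))))
})

test_that("ld_catalogue_scan applies window, r2 and significance rules", {
  set.seed(77)
  n <- 300L
  nrs <- matrix(rbinom(n, 2L, 0.4), 1,
                dimnames = list("GNRS_1", paste0("s", 1:n)))
  loci <- data.frame(gnrs_id = "GNRS_1", chrom = "chr1", pos = 500000L,
                     stringsAsFactors = FALSE)
  snp <- rbind(tag = nrs[1, ],                       # r2 = 1, 50 kb away
               far = nrs[1, ],                       # r2 = 1 but 150 kb
               weak = ifelse(runif(n) < 0.5, nrs[1, ],
                             rbinom(n, 2L, 0.4)))    # r2 ~ 0.25
  colnames(snp) <- colnames(nrs)
  cat_ <- data.frame(snp_id = c("tag", "far", "weak"), chrom = "chr1",
                     pos = c(550000L, 650000L, 510000L),
                     p = c(1e-9, 1e-9, 1e-9), stringsAsFactors = FALSE)
  out <- ld_catalogue_scan(nrs, loci, snp, cat_)
  expect_equal(out$snp_id, "tag")
  # non-significant SNPs never pair
  cat2 <- cat_; cat2$p <- 0.5
  expect_equal(nrow(ld_catalogue_scan(nrs, loci, snp, cat2)), 0L)
})

test_that("bh_fdr matches the hand step-up", {
  b <- bh_fdr(0.01, 0.05)
  expect_true(b$significant)
  r <- bh_fdr(c(0.001, 0.02, 0.9), 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 5), 0.05)$significant))
  set.seed(78)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05)$significant, bh_oracle(p, 0.05))
  }
})
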