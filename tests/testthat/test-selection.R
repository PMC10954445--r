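# Simulated two-population dosage matrix: n per population, loci with a
# per-population AF drawn around a divergence level.
sim_two_pops <- function(n_loci, n_per_pop, fst_like = 0.3, seed = 1) {
  set.seed(seed)
  p <- runif(n_loci, 0.2, 0.8)
  a <- plogis(qlogis(p) + rnorm(n_loci, 0, fst_like * 4))
  b <- plogis(qlogis(p) - rnorm(n_loci, 0, fst_like * 4))
  d <- cbind(
    vapply(seq_len(n_per_pop), function(i) rbinom(n_loci, 2L, a),
           integer(n_loci)),
    vapply(seq_len(n_per_pop), function(i) rbinom(n_loci, 2L, b),
           integer(n_loci)))
  dimnames(d) <- list(paste0("L", seq_len(n_loci)),
                      paste0("s", seq_len(2 * n_per_pop)))
  d
}

test_that("genotype_pca separates diverged populations", {
  d <- sim_two_pops(300, 40, fst_like = 0.5, seed = 9)
  pca <- genotype_pca(d, maf_min = 0.05, n_components = 2L)
  grp <- rep(c("A", "B"), each = 40)
  x <- pca$scores[, 1]
  # silhouette on PC1
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[grp == grp[i]][-match(i, which(grp == grp[i]))]))
    oth <- mean(abs(x[i] - x[grp != grp[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)

  # permuted sample order: identical scores under reordering
  perm <- sample(ncol(d))
  pca2 <- genotype_pca(d[, perm], maf_min = 0.05, n_components = 2L)
  expect_equal(pca2$scores[colnames(d), ], pca$scores,
               tolerance = 1e-8)

  same <- matrix(1L, 10, 20,
                 dimnames = list(paste0("L", 1:10), paste0("s", 1:20)))
  expect_error(genotype_pca(same), "filters|variance")
})

test_that("hudson_fst matches the stated formula", {
  # equal frequencies: estimator ~ 0 (small negative finite-sample bias)
  expect_lt(abs(hudson_fst(500, 1000, 500, 1000)), 0.01)
  expect_equal(hudson_fst(50, 50, 0, 50), 1)
  # direct formula evaluation at p1=0.8, p2=0.2, 50 alleles each
  p1 <- 0.8; p2 <- 0.2; n1 <- 50; n2 <- 50
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hudson_fst(40, 50, 10, 50), N / D)
  expect_true(is.na(hudson_fst(0, 50, 0, 50)))  # D = 0 undefined
})

test_that("pbs closed forms and monotonicity", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(pbs(0.1, 0.1, 0.1), 0.05268, tolerance = 1e-4)
  grid <- seq(0, 0.8, by = 0.1)
  base <- pbs(0.3, 0.3, 0.3)
  expect_true(all(diff(pbs(grid, 0.3, 0.3)) > 0))
  expect_true(all(diff(pbs(0.3, grid, 0.3)) > 0))
  expect_true(all(diff(pbs(0.3, 0.3, grid)) < 0))
  # clamping keeps PBS finite at FST = 1
  expect_true(is.finite(pbs(1, 1, 0)))
})

mk_panel <- function(n, pops, platforms = "ONT") {
  data.frame(sample = paste0("s", seq_len(n * length(pops))),
             population = rep(pops, each = n),
             platform = rep_len(platforms, n * length(pops)),
             sex = "F", trio_id = NA, trio_role = NA,
             stringsAsFactors = FALSE)
}

sim_three_pops <- function(n_loci, n, planted = NULL, seed = 1) {
  set.seed(seed)
  p <- runif(n_loci, 0.05, 0.95)
  afs <- cbind(A = p, B = p, C = p)
  if (!is.null(planted)) afs[planted, ] <- c(0.9, 0.05, 0.05)
  d <- do.call(cbind, lapply(c("A", "B", "C"), function(pp)
    vapply(seq_len(n), function(i) rbinom(n_loci, 2L, afs[, pp]),
           integer(n_loci))))
  dimnames(d) <- list(paste0("L", seq_len(n_loci)),
                      paste0("s", seq_len(3 * n)))
  d
}

test_that("pbs_scan finds a planted selection locus by downsampling consensus", {
  n_loci <- 1500L
  d <- sim_three_pops(n_loci, 60, planted = 1L, seed = 33)
  panel <- mk_panel(60, c("A", "B", "C"))
  loci <- data.frame(gnrs_id = rownames(d), chrom = "chr1",
                     pos = seq_len(n_loci) * 2000L,
                     stringsAsFactors = FALSE)
  sc <- pbs_scan(d, loci, panel, "A", "B", "C", downsample_to = 40L,
                 seed = 5L)
  expect_true(sc$results$candidate[1])
  expect_true("L1" %in% sc$signals$gnrs_id)
  # neutral loci: candidate count bounded by the top-quantile mass
  expect_lte(sum(sc$results$candidate), ceiling(0.001 * n_loci) + 1L)
})

test_that("pbs_scan is replicate-invariant without downsampling and merges signals", {
  n_loci <- 400L
  d <- sim_three_pops(n_loci, 30, planted = NULL, seed = 44)
  panel <- mk_panel(30, c("A", "B", "C"))
  loci <- data.frame(gnrs_id = rownames(d), chrom = "chr1",
                     pos = seq_len(n_loci) * 2000L,
                     stringsAsFactors = FALSE)
  sc <- pbs_scan(d, loci, panel, "A", "B", "C", downsample_to = 30L,
                 replicates = 10L, seed = 6L)
  # downsample_to = full population size: every replicate identical
  expect_true(all(sc$results$n_hits %in% c(0L, 10L)))

  # two planted loci 500 kb apart merge into one signal
  d2 <- sim_three_pops(n_loci, 60, planted = c(1L, 2L), seed = 45)
  loci2 <- loci
  loci2$pos[1:2] <- c(1000000L, 1500000L)
  sc2 <- pbs_scan(d2, loci2, mk_panel(60, c("A", "B", "C")),
                  "A", "B", "C", downsample_to = 40L, seed = 7L)
  if (all(c("L1", "L2") %in%
            sc2$results$gnrs_id[sc2$results$candidate])) {
    sig <- sc2$signals[sc2$signals$gnrs_id %in% c("L1", "L2"), ]
    expect_equal(nrow(sig), 1L)
    expect_equal(sig$n_loci, 2L)
  }
})

test_that("batch_effect_filter flags platform-determined genotypes only", {
  set.seed(61)
  n <- 60L
  panel <- mk_panel(n, "A", platforms = c("ONT", "HiFi"))
  plat <- panel$platform
  d <- rbind(
    BAD = ifelse(plat == "ONT", 2L, 0L),
    do.call(rbind, lapply(1:50, function(i) rbinom(n, 2L, 0.4))))
  rownames(d) <- c("BAD", paste0("L", 1:50))
  colnames(d) <- panel$sample
  q <- batch_effect_filter(d, panel)$q
  expect_lt(q[1], 0.05)
  expect_lte(mean(q[-1] < 0.05, na.rm = TRUE), 0.1)

  # single-platform population: nothing testable
  panel1 <- mk_panel(n, "A", platforms = "ONT")
  expect_true(all(is.na(batch_effect_filter(d, panel1)$q)))
})
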