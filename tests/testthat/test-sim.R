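test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 120000L,
                    n_samples_per_population = c(EAS = 2L, AFR = 2L),
                    n_trios = 0L, n_events = 8L, n_selection = 0L,
                    n_genes_per_chrom = 3L, seed = 7L)
  r1 <- build_reference(cfg); r2 <- build_reference(cfg)
  expect_identical(r1$seqs, r2$seqs)
  t1 <- simulate_population(r1, cfg)
  t2 <- simulate_population(r2, cfg)
  expect_identical(t1$presence, t2$presence)
  a1 <- emit_assemblies(r1, t1, cfg, samples = t1$panel$sample[1])
  a2 <- emit_assemblies(r2, t2, cfg, samples = t2$panel$sample[1])
  expect_identical(a1$samples[[1]]$contigs, a2$samples[[1]]$contigs)

  cfg2 <- sim_config(n_chromosomes = 2L, chrom_length = 120000L,
                     n_samples_per_population = c(EAS = 2L, AFR = 2L),
                     n_trios = 0L, n_events = 8L, n_selection = 0L,
                     n_genes_per_chrom = 3L, seed = 8L)
  expect_false(identical(build_reference(cfg2)$seqs, r1$seqs))
})

test_that("reference satellites are exact tandem arrays and config validates", {
  w <- small_world()
  sat <- w$ref$satellites
  expect_gte(nrow(sat), 1L)
  for (i in seq_len(nrow(sat))) {
    arr <- substr(w$ref$seqs[[sat$chrom[i]]], sat$start[i] + 1, sat$end[i])
    mono <- w$ref$satellite_library[[sat$monomer[i]]]
    expect_equal(arr, substr(strrep(mono, ceiling(nchar(arr) / nchar(mono))),
                             1, nchar(arr)))
  }
  tab <- data.frame(event_id = "E1", class = "unique_novel", length = 100L,
                    af_EAS = 1.5, af_AFR = 0.1, selection = FALSE)
  expect_error(sim_config(n_samples_per_population = c(EAS = 2L, AFR = 2L),
                          nrs_event_table = tab), "\\[0, 1\\]")
  tab$af_EAS <- 0.5; tab$length <- 20L
  expect_error(sim_config(n_samples_per_population = c(EAS = 2L, AFR = 2L),
                          nrs_event_table = tab), "50 bp")
  expect_error(build_reference(sim_config(chrom_length = 100000L,
                                          n_genes_per_chrom = 200L,
                                          seed = 1L)),
               "too small")
})

test_that("presence follows the configured allele frequencies", {
  mk <- function(af1, af2) data.frame(
    event_id = c("E1", "E2"), class = "unique_novel", length = 80L,
    af_EAS = af1, af_AFR = af2, selection = FALSE,
    stringsAsFactors = FALSE)
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 120000L,
                    n_samples_per_population = c(EAS = 4L, AFR = 4L),
                    n_trios = 0L, nrs_event_table = mk(c(1, 0), c(1, 0)),
                    n_genes_per_chrom = 3L, seed = 3L)
  ref <- build_reference(cfg)
  truth <- simulate_population(ref, cfg)
  d <- truth_dosage(truth)
  expect_true(all(d["E1", ] == 2L))   # AF 1 everywhere: homozygous in all
  expect_true(all(d["E2", ] == 0L))   # AF 0: absent everywhere
})

test_that("empirical AF converges to the configured AF (binomial check)", {
  tab <- data.frame(event_id = "E1", class = "unique_novel", length = 60L,
                    af_POP = 0.3, selection = FALSE)
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 120000L,
                    n_samples_per_population = c(POP = 5000L),
                    n_trios = 0L, nrs_event_table = tab,
                    n_genes_per_chrom = 3L, seed = 13L)
  ref <- build_reference(cfg)
  truth <- simulate_population(ref, cfg)
  af_hat <- mean(truth$presence["E1", , ])
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_lt(abs(af_hat - 0.3), 3 * se)
})

test_that("trio offspring are Mendelian-consistent before any noise", {
  w <- small_world()
  d <- truth_dosage(w$truth)
  mer <- mendelian_error_rate(d, w$truth$pedigree)
  expect_identical(mer$n_errors, 0L)
  expect_gt(mer$n_evaluated, 0L)
  # haplotype-level: child haplotype 1 must be carriable by the father
  ped <- w$truth$pedigree[1, ]
  fa_d <- d[, ped$father]
  ch1 <- w$truth$presence[, ped$child, 1]
  expect_true(all(!(ch1 & fa_d == 0L)))
})

test_that("assemblies embed events with flanks; knobs behave", {
  w <- small_world()
  # unfragmented emission: a heterozygous carrier has a contig containing
  # the full event with >= 1 kb flank on both sides
  cfg0 <- w$cfg; cfg0$fragment_rate <- 0; cfg0$contaminant_fraction <- 0
  d <- truth_dosage(w$truth)
  ei <- which(rowSums(d >= 1) > 0)[5]
  ev <- w$truth$events[ei, ]
  carrier <- names(which(d[ev$event_id, ] >= 1))[1]
  asm0 <- emit_assemblies(w$ref, w$truth, cfg0, samples = carrier)
  hit <- vapply(asm0$samples[[carrier]]$contigs, function(s)
    grepl(ev$seq, s, fixed = TRUE), logical(1))
  expect_true(any(hit))
  expect_length(asm0$labels$contaminant_contigs, 0L)
  # depth bait carries 3.5x depth in the track
  bait <- w$asm$labels$depth_bait
  if (!is.null(bait)) {
    dep <- w$asm$samples[[bait$sample[1]]]$depth
    expect_equal(dep$depth[match(bait$contig[1], dep$contig)],
                 3.5 * w$cfg$depth_mean)
  }
})

test_that("expression simulation: planted dosage effects are exact without noise", {
  w <- small_world()
  ex <- simulate_expression(w$truth, w$cfg, noise_sd = 0)
  d <- truth_dosage(w$truth)
  eff <- ex$effects[1, ]
  y <- ex$expr[eff$transcript, ]
  g <- d[eff$event_id, ]
  base <- unique(round(y - eff$beta * g, 9))
  expect_length(base, 1L)   # baseline + beta * dosage exactly
  bad <- w$cfg
  bad$eqtl_effects <- data.frame(event_id = w$truth$events$event_id[1],
                                 transcript = "NOPE", beta = 1)
  expect_error(simulate_expression(w$truth, bad), "TSS")
})

test_that("snp panel hits the target LD", {
  tab <- data.frame(event_id = sprintf("E%d", 1:3),
                    class = "unique_novel", length = 60L,
                    af_POP = c(0.4, 0.3, 0.5), selection = FALSE)
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 200000L,
                    n_samples_per_population = c(POP = 250L), n_trios = 0L,
                    nrs_event_table = tab, n_genes_per_chrom = 3L,
                    snp_panel = list(n_snps = 20L, target_r2 = 1,
                                     max_dist = 50000L),
                    seed = 21L)
  ref <- build_reference(cfg)
  truth <- simulate_population(ref, cfg)
  sp <- simulate_snp_panel(truth, cfg)
  d <- truth_dosage(truth)
  tagged <- which(!is.na(sp$catalogue$tagged_event))
  for (i in tagged) {
    expect_identical(unname(sp$genotypes[i, ]),
                     unname(d[sp$catalogue$tagged_event[i], ]))
  }
  # target r2 = 0: independent SNPs
  cfg0 <- cfg
  cfg0$snp_panel <- list(n_snps = 20L, target_r2 = 0, max_dist = 50000L)
  sp0 <- simulate_snp_panel(truth, cfg0)
  t0 <- which(!is.na(sp0$catalogue$tagged_event))[1]
  r2 <- ld_r2(sp0$genotypes[t0, ], d[sp0$catalogue$tagged_event[t0], ])
  expect_lt(r2, 0.1)
  # a tag configured beyond 100 kb must be rejected
  cfgbad <- cfg
  cfgbad$snp_panel$tags <- data.frame(event_id = "E1", offset = 150000L,
                                      r2 = 1)
  expect_error(simulate_snp_panel(truth, cfgbad), "100 kb")
})

test_that("written simulation round-trips through the standard formats", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_simulation(w$ref, w$truth, w$cfg, dir)
  fa <- read_fasta(file.path(dir, "reference.fa"))
  expect_identical(unname(fa), unname(w$ref$seqs))
  vcf <- read_vcf(file.path(dir, "truth.vcf"))
  expect_equal(nrow(vcf), nrow(w$truth$events))
  expect_equal(vcf$pos, w$truth$events$pos)
  expect_equal(substr(vcf$alt, 2, nchar(vcf$alt)), w$truth$events$seq)
  panel <- read_tsv(file.path(dir, "panel.tsv"))
  expect_equal(panel$sample, w$truth$panel$sample)
  expect_true(file.exists(file.path(dir, "config.yaml")))
})
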