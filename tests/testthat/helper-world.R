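# Shared fixtures, built once per test run and cached in this environment.
.world_cache <- new.env(parent = emptyenv())

# Small simulated world: 1 chromosome x 200 kb, 2 populations x 3 samples
# plus one trio, 20 planted events, contaminants and depth bait on.
small_world <- function() {
  if (!is.null(.world_cache$small)) return(.world_cache$small)
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 200000L,
                    n_samples_per_population = c(EAS = 3L, AFR = 3L),
                    n_trios = 1L, n_events = 20L, n_selection = 0L,
                    contaminant_fraction = 0.1, n_genes_per_chrom = 6L,
                    seed = 11L)
  ref <- build_reference(cfg)
  truth <- simulate_population(ref, cfg)
  asm <- emit_assemblies(ref, truth, cfg)
  .world_cache$small <- list(cfg = cfg, ref = ref, truth = truth,
                             asm = asm, index = build_target_index(ref),
                             profiles = composition_profiles(ref))
  .world_cache$small
}

# Catalogue built directly from truth events (bypasses discovery), for
# genotyping / popstats tests.
truth_catalogue <- function(truth) {
  ev <- truth$events
  recs <- data.frame(chrom = ev$chrom, pos = ev$pos, seq = ev$seq,
                     rep_sample = NA_character_, tie_break = "truth",
                     n_supports = 1L, supports = "",
                     multi_allelic = FALSE, stringsAsFactors = FALSE)
  cat_ <- build_catalogue(recs)
  cat_$event_id <- ev$event_id[order(ev$chrom, ev$pos)]
  cat_
}

# Independent Needleman-Wunsch oracle under the +2/-1/-0.5 scheme
# (linear gaps), used to brute-force representative selection.
nw_score_oracle <- function(a, b, match = 2, mismatch = -1, gap = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  M <- matrix(0, na + 1, nb + 1)
  M[, 1] <- -gap * (0:na); M[1, ] <- -gap * (0:nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    M[i + 1, j + 1] <- max(
      M[i, j] + if (ca[i] == cb[j]) match else mismatch,
      M[i, j + 1] - gap, M[i + 1, j] - gap)
  }
  M[na + 1, nb + 1]
}

random_dna_test <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Random primitive motif (no smaller period divides it).
random_primitive_motif <- function(len) {
  repeat {
    m <- random_dna_test(len)
    if (nchar(nrskit:::primitive_motif(m)) == len) return(m)
  }
}

# Independent step-up BH oracle.
bh_oracle <- function(p, level = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- level * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  sig <- logical(m)
  if (is.finite(k)) sig[o[seq_len(k)]] <- TRUE
  sig
}

# Brute-force optimal clustering oracle: minimum number of groups of
# 1-D points such that each group's diameter is <= max_dist (interval
# partition enumeration over sorted points).
min_clusters_oracle <- function(pos, max_dist = 250) {
  pos <- sort(pos)
  n <- length(pos)
  best <- rep(Inf, n + 1); best[1] <- 0
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (pos[i] - pos[j] <= max_dist)
      best[i + 1] <- min(best[i + 1], best[j] + 1)
  }
  best[n + 1]
}

# Exact HWE oracle: enumerate every genotype configuration with the same
# sample size and allele count; p = sum of probabilities of
# configurations no more probable than the observed.
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  na <- 2 * hom_alt + het
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    rr <- n - h - aa
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(rr) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(het, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}
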