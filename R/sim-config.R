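#' Simulation configuration
#'
#' [sim_config()] assembles and validates the full description of a
#' simulated world: reference geometry, population panel, planted
#' nonreference-sequence (NRS) events with per-population allele
#' frequencies, trios, contamination and depth artefacts, and planted
#' eQTL/GWAS/SNP-tag effects.  All downstream randomness derives from the
#' single `seed` through named substreams, so a fixed config reproduces
#' byte-identical outputs.
#'
#' Defaults describe the bundled desk-scale panel: 2 chromosomes of 1 Mb,
#' three populations (EAS/AFR/AMR) of 20 samples each, 2 trios, 300
#' planted events of 50 bp to 3 kb, 20x depth and 5% contaminant contigs.
#'
#' @param n_chromosomes,chrom_length reference geometry.
#' @param n_samples_per_population named integer vector.
#' @param n_trios number of trios; each adds one offspring sample whose
#'   parents are the first two samples of a population.
#' @param n_events number of planted events when `nrs_event_table` is not
#'   supplied.
#' @param nrs_event_table optional data frame (class, length, af_<pop>...).
#' @param n_selection number of planted selection events (focal AF 0.9 vs
#'   0.05 elsewhere).
#' @param contaminant_fraction fraction of contigs that are contaminants.
#' @param depth_mean mean fold-coverage of the simulated depth tracks.
#' @param depth_bait_fraction fraction of event-carrying contigs given a
#'   3.5x depth to exercise the depth filter.
#' @param fragment_rate expected contig breakpoints per bp (Poisson).
#' @param platform_levels platforms cycled over within each population.
#' @param n_genes_per_chrom annotated genes (and transcripts) per
#'   chromosome.
#' @param eqtl_effects,gwas_effects optional data frames of planted
#'   associations; sensible defaults are generated when `NULL`.
#' @param snp_panel list(n_snps, target_r2, max_dist) for the tag-SNP
#'   simulator.
#' @param min_event_length smallest plantable event (>= 50 bp).
#' @param seed master seed (integer).
#' @return validated object of class `nrs_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 1000000L,
                       n_samples_per_population = c(EAS = 20L, AFR = 20L,
                                                    AMR = 20L),
                       n_trios = 2L, n_events = 300L,
                       nrs_event_table = NULL, n_selection = 3L,
                       contaminant_fraction = 0.05, depth_mean = 20,
                       depth_bait_fraction = 0.01,
                       fragment_rate = 3e-06,
                       platform_levels = c("ONT", "HiFi"),
                       n_genes_per_chrom = 25L,
                       eqtl_effects = NULL, gwas_effects = NULL,
                       snp_panel = list(n_snps = 100L, target_r2 = 0.9,
                                        max_dist = 100000L),
                       min_event_length = 50L, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 100000L,
            length(n_samples_per_population) >= 1L,
            !is.null(names(n_samples_per_population)),
            n_trios >= 0L, contaminant_fraction >= 0,
            contaminant_fraction <= 1, depth_mean > 0,
            min_event_length >= 50L)
  pops <- names(n_samples_per_population)
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_samples_per_population = n_samples_per_population,
    n_trios = as.integer(n_trios),
    n_selection = as.integer(n_selection),
    contaminant_fraction = contaminant_fraction,
    depth_mean = depth_mean,
    depth_bait_fraction = depth_bait_fraction,
    fragment_rate = fragment_rate,
    platform_levels = platform_levels,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    snp_panel = snp_panel,
    min_event_length = as.integer(min_event_length),
    seed = as.integer(seed)), class = "nrs_sim_config")
  cfg$nrs_event_table <- nrs_event_table %||%
    default_event_table(n_events, pops, n_selection, min_event_length, seed)
  af_cols <- paste0("af_", pops)
  if (!all(af_cols %in% names(cfg$nrs_event_table)))
    stop("event table lacks per-population AF columns: ",
         paste(setdiff(af_cols, names(cfg$nrs_event_table)), collapse = ", "))
  afs <- as.matrix(cfg$nrs_event_table[, af_cols])
  if (any(afs < 0 | afs > 1)) stop("allele frequencies must lie in [0, 1]")
  if (any(cfg$nrs_event_table$length < 50L))
    stop("planted events must be at least 50 bp")
  if (!is.null(snp_panel$max_dist) && snp_panel$max_dist > 100000L)
    stop("tag SNPs must be placed within 100 kb of their NRS")
  cfg$eqtl_effects <- eqtl_effects
  cfg$gwas_effects <- gwas_effects
  cfg
}

# Default planted-event table: class mix spanning the repeat-heavy
# composition of real nonreference callsets (tandem arrays, mobile-element
# derived copies, unique novel sequence), lengths 50 bp - 3 kb, and
# per-population AFs from a U-shaped Beta(0.4, 1.2) so singletons and
# common events both occur.  Selection events get AF 0.9 in the first
# population vs 0.05 elsewhere.
default_event_table <- function(n_events, pops, n_selection,
                                min_len, seed) {
  with_substream(seed, "event_table", {
    class <- sample(c("tandem_repeat", "mobile_element_like",
                      "unique_novel"), n_events, replace = TRUE,
                    prob = c(0.45, 0.30, 0.25))
    len <- pmax(min_len,
                as.integer(round(exp(runif(n_events, log(min_len),
                                           log(3000))))))
    af <- matrix(round(rbeta(n_events * length(pops), 0.4, 1.2), 4),
                 nrow = n_events)
    colnames(af) <- paste0("af_", pops)
    sel <- rep(FALSE, n_events)
    if (n_selection > 0L) {
      pick <- sample(n_events, min(n_selection, n_events))
      sel[pick] <- TRUE
      af[pick, ] <- 0.05
      af[pick, 1L] <- 0.9
    }
    data.frame(event_id = sprintf("EV%04d", seq_len(n_events)),
               class = class, length = len, af, selection = sel,
               stringsAsFactors = FALSE)
  })
}

#' @importFrom stats rbeta
NULL
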