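#' Discover the population catalogue from assemblies
#'
#' Runs extraction (with depth, satellite and contamination filters) and
#' anchoring per sample, then merges the pooled calls into the
#' nonredundant catalogue.  This is the extract -> anchor -> merge core
#' shared by [run_pipeline()], the test suite and the acceptance script.
#'
#' @param ref reference object.
#' @param assemblies [emit_assemblies()] output (or a compatible list).
#' @param config simulation / pipeline config (for the seed only).
#' @param profiles composition profiles (default
#'   [composition_profiles()] of `ref`).
#' @param progress print one audit line per sample.
#' @return list with `catalogue`, per-sample `placed`/`unplaced` pools,
#'   the filter `audit` table and cached `alignments` per sample.
#' @export
discover_catalogue <- function(ref, assemblies, config,
                               profiles = composition_profiles(ref),
                               progress = FALSE) {
  index <- build_target_index(ref)
  placed_all <- list(); unplaced_all <- list(); audit <- list()
  alns <- list()
  for (smp in names(assemblies$samples)) {
    a <- assemblies$samples[[smp]]
    segs <- extract_unaligned(a$contigs, index, depth = a$depth,
                              sample = smp)
    alns[[smp]] <- attr(segs, "alignments")
    mean_depth <- sum(a$depth$depth * (a$depth$end - a$depth$start)) /
      sum(a$depth$end - a$depth$start)
    segs <- depth_filter(segs, mean_depth)
    segs <- satellite_filter(segs, ref$satellite_library)
    segs <- contamination_filter(segs, profiles$host, profiles$foreign,
                                 index)
    audit[[smp]] <- segs[, c("segment_id", "sample", "contig", "start",
                             "end", "length", "flag_depth",
                             "flag_satellite", "flag_contaminant")]
    anch <- anchor_segments(segs, a$contigs, index)
    placed_all[[smp]] <- anch$placed
    unplaced_all[[smp]] <- anch$unplaced
    if (progress)
      message(sprintf("%s: %d segments, %d placed, %d unplaced", smp,
                      nrow(segs), nrow(anch$placed),
                      nrow(anch$unplaced)))
  }
  placed <- do.call(rbind, placed_all)
  unplaced <- do.call(rbind, unplaced_all)
  up_records <- NULL
  if (!is.null(unplaced) && nrow(unplaced) > 0L) {
    uf <- filter_unplaced(unplaced, index, ref$satellite_library)
    up_records <- merge_unplaced(uf[uf$retained & !uf$flag_singleton, ,
                                    drop = FALSE])
  }
  catalogue <- NULL
  if (!is.null(placed) && nrow(placed) > 0L) {
    clusters <- cluster_placed(placed)
    reps <- select_representatives(clusters)
    catalogue <- build_catalogue(reps, up_records)
  }
  list(catalogue = catalogue, placed = placed, unplaced = unplaced,
       audit = do.call(rbind, audit), alignments = alns)
}

#' Run the full pipeline on a simulated world
#'
#' simulate -> extract -> anchor -> merge -> genotype -> stats, writing
#' each stage's artefacts as plain text under `out_dir` together with a
#' MANIFEST of completed stages.  Identical config (and seed) reproduces
#' identical outputs.
#'
#' @param config [sim_config()] object.
#' @param out_dir output directory.
#' @param genotype_mode `"contigs"` (breakpoint evidence) or `"truth"`
#'   (noise-free haplotype lookup).
#' @param run_scans also run the inference layers (PBS scan, cis-eQTL on
#'   simulated expression, GWAS on simulated phenotypes, SNP LD) and
#'   write their tables (default FALSE).
#' @param progress print per-stage audit lines.
#' @return list with all stage objects (invisibly also on disk).
#' @export
run_pipeline <- function(config, out_dir,
                         genotype_mode = c("contigs", "truth"),
                         run_scans = FALSE, progress = FALSE) {
  genotype_mode <- match.arg(genotype_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  prov <- c(sprintf("nrskit seed=%d", config$seed),
            sprintf("chromosomes=%d x %d bp", config$n_chromosomes,
                    config$chrom_length))
  ref <- build_reference(config)
  truth <- simulate_population(ref, config)
  asm <- emit_assemblies(ref, truth, config)
  write_simulation(ref, truth, config, file.path(out_dir, "sim"))
  note("simulate")
  disc <- discover_catalogue(ref, asm, config, progress = progress)
  write_tsv(disc$audit, file.path(out_dir, "filter_audit.tsv"), prov)
  note("extract")
  write_tsv(disc$placed, file.path(out_dir, "placed.tsv"), prov)
  if (!is.null(disc$unplaced) && nrow(disc$unplaced))
    write_tsv(disc$unplaced, file.path(out_dir, "unplaced.tsv"), prov)
  note("anchor")
  cat_ <- disc$catalogue
  if (is.null(cat_)) stop("no placed calls; cannot build a catalogue")
  note("merge")
  samples <- truth$panel$sample
  geno <- matrix("./.", nrow(cat_), length(samples),
                 dimnames = list(cat_$gnrs_id, samples))
  for (smp in samples) {
    g <- if (genotype_mode == "truth")
      genotype_sample(NULL, cat_, ref, truth = truth, sample = smp)
    else
      genotype_sample(asm$samples[[smp]]$contigs, cat_, ref,
                      alignments = disc$alignments[[smp]])
    geno[, smp] <- g$geno
  }
  dosage <- geno_to_dosage(geno)
  note("genotype")
  af <- compute_af(dosage, truth$panel)
  write_catalogue_vcf(cat_, ref, file.path(out_dir, "catalogue.vcf"),
                      af_records = af, provenance = prov)
  unp <- cat_[!cat_$placed, , drop = FALSE]
  if (nrow(unp))
    write_fasta(setNames(unp$seq, unp$gnrs_id),
                file.path(out_dir, "catalogue_unplaced.fa"))
  per_sample <- colSums(dosage > 0L, na.rm = TRUE)
  stats_tab <- data.frame(
    category = c("placed", "unplaced", "total"),
    n = c(sum(cat_$placed), sum(!cat_$placed), nrow(cat_)),
    total_length = c(sum(cat_$length[cat_$placed]),
                     sum(cat_$length[!cat_$placed]), sum(cat_$length)),
    average_length = round(c(
      mean(cat_$length[cat_$placed]),
      if (any(!cat_$placed)) mean(cat_$length[!cat_$placed]) else NA,
      mean(cat_$length))),
    n50 = c(compute_n50(cat_$length[cat_$placed]),
            if (any(!cat_$placed)) compute_n50(cat_$length[!cat_$placed])
            else NA, compute_n50(cat_$length)),
    nrs_per_sample = round(mean(per_sample)),
    samples_per_nrs = round(mean(cat_$n_supports)))
  write_tsv(stats_tab, file.path(out_dir, "summary.tsv"), prov)
  write_tsv(af, file.path(out_dir, "af.tsv"), prov)
  note("stats")
  scans <- NULL
  if (run_scans) {
    loci <- cat_[, c("gnrs_id", "chrom", "pos", "multi_allelic")]
    pops <- unique(truth$panel$population)
    if (length(pops) >= 3L) {
      sc <- pbs_scan(dosage, loci, truth$panel, pops[1], pops[2],
                     pops[3], seed = config$seed)
      write_tsv(sc$results, file.path(out_dir, "pbs.tsv"), prov)
      if (!is.null(sc$signals))
        write_tsv(sc$signals, file.path(out_dir, "pbs_signals.tsv"),
                  prov)
    } else sc <- NULL
    ex <- simulate_expression(truth, config)
    eq <- cis_eqtl_scan(ex$expr, dosage, ex$tss, loci,
                        covariates = NULL, n_pcs = 2L)
    write_tsv(eq, file.path(out_dir, "eqtl.tsv"), prov)
    ph <- simulate_phenotypes(truth, config)
    quant <- names(ph$trait_types)[ph$trait_types == "quantitative"]
    gw <- gwas(dosage, ph$phenotypes,
               traits = setNames(rep("quantitative", length(quant)),
                                 quant))
    write_tsv(gw$results, file.path(out_dir, "gwas.tsv"), prov)
    sp <- simulate_snp_panel(truth, config)
    ld <- ld_catalogue_scan(dosage, loci, sp$genotypes, sp$catalogue)
    write_tsv(ld, file.path(out_dir, "ld.tsv"), prov)
    scans <- list(pbs = sc, eqtl = eq, gwas = gw, ld = ld)
    note("scans")
  }
  invisible(list(ref = ref, truth = truth, assemblies = asm,
                 discovery = disc, catalogue = cat_, genotypes = geno,
                 dosage = dosage, af = af, scans = scans))
}

#' Match catalogue records to planted truth events
#'
#' A record recovers an event when it is placed on the event's
#' chromosome within `tol` bp of the planted insertion point.
#'
#' @param catalogue `nrs_catalogue`.
#' @param truth `nrs_truth`.
#' @param tol matching tolerance in bp (default 20).
#' @return data frame per event: `n_records` matching and the matched
#'   record ids.
#' @export
match_truth <- function(catalogue, truth, tol = 20L) {
  pl <- catalogue[catalogue$placed, , drop = FALSE]
  ev <- truth$events
  do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    hit <- which(pl$chrom == ev$chrom[i] & abs(pl$pos - ev$pos[i]) <= tol)
    data.frame(event_id = ev$event_id[i], n_records = length(hit),
               records = paste(pl$gnrs_id[hit], collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
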