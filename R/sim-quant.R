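#' Simulate transcript expression with planted cis effects
#'
#' Expression of transcript j in sample i is
#' `baseline_j + beta * dosage(event) + N(0, 1)` for planted pairs and
#' baseline plus noise otherwise.  One transcript is simulated per
#' annotated gene; the TSS table travels with the truth object.
#'
#' @param truth `nrs_truth` object.
#' @param config `nrs_sim_config`; `config$eqtl_effects` may name planted
#'   (event_id, transcript, beta) rows, otherwise 3 default pairs with
#'   standardized beta 1.5 are planted on common events.
#' @param noise_sd standard deviation of the Gaussian noise (default 1;
#'   0 gives exact baseline + beta * dosage values).
#' @return list with `expr` (transcripts x samples matrix), `effects`
#'   (planted pairs) and `tss` (transcript TSS table).
#' @export
simulate_expression <- function(truth, config, noise_sd = 1) {
  genes <- truth$genes
  if (is.null(genes) || nrow(genes) == 0L) stop("truth carries no TSS table")
  dos <- truth_dosage(truth)
  eff <- config$eqtl_effects %||%
    default_planted_effects(truth, n = 3L, beta = 1.5, seed = config$seed,
                            stream = "eqtl_effects")
  if (!all(eff$transcript %in% genes$gene_id))
    stop("planted transcript without TSS annotation: ",
         paste(setdiff(eff$transcript, genes$gene_id), collapse = ", "))
  with_substream(config$seed, "expression", {
    baseline <- rnorm(nrow(genes), 10, 2)
    expr <- matrix(rnorm(nrow(genes) * ncol(dos), 0, noise_sd),
                   nrow = nrow(genes),
                   dimnames = list(genes$gene_id, colnames(dos)))
    expr <- expr + baseline
    for (i in seq_len(nrow(eff)))
      expr[eff$transcript[i], ] <- expr[eff$transcript[i], ] +
        eff$beta[i] * dos[eff$event_id[i], ]
    list(expr = expr, effects = eff,
         tss = genes[, c("gene_id", "chrom", "tss")])
  })
}

# Pick planted association targets: common events (overall dosage MAF in
# [0.15, 0.45]) paired with the nearest annotated gene on their
# chromosome.
default_planted_effects <- function(truth, n, beta, seed, stream) {
  dos <- truth_dosage(truth)
  offspring <- truth$panel$sample[truth$panel$trio_role %in% "offspring"]
  keep <- setdiff(colnames(dos), offspring)
  af <- rowMeans(dos[, keep, drop = FALSE]) / 2
  maf <- pmin(af, 1 - af)
  cand <- which(maf >= 0.15 & maf <= 0.45)
  with_substream(seed, stream, {
    pick <- sample(cand, min(n, length(cand)))
    ev <- truth$events[pick, , drop = FALSE]
    transcript <- vapply(seq_len(nrow(ev)), function(i) {
      g <- truth$genes[truth$genes$chrom == ev$chrom[i], , drop = FALSE]
      g$gene_id[which.min(abs(g$tss - ev$pos[i]))]
    }, character(1))
    data.frame(event_id = ev$event_id, transcript = transcript,
               beta = beta, stringsAsFactors = FALSE)
  })
}

#' Simulate phenotypes with covariates and planted genetic effects
#'
#' Quantitative traits are `b_age*age + b_sex*sex + b_bmi*bmi +
#' beta*dosage + N(0,1)`; binary traits use the logistic link on the same
#' linear predictor.
#'
#' @param truth,config simulation objects; `config$gwas_effects` may give
#'   planted (event_id, trait, beta) rows (default: one quantitative
#'   trait effect, beta 1.2).
#' @param noise_sd residual standard deviation for quantitative traits.
#' @return list with `phenotypes` (data frame: sample, age, sex, bmi and
#'   one column per trait), `effects`, `trait_types`.
#' @export
simulate_phenotypes <- function(truth, config, noise_sd = 1) {
  dos <- truth_dosage(truth)
  eff <- config$gwas_effects %||% {
    e <- default_planted_effects(truth, n = 1L, beta = 1.2,
                                 seed = config$seed,
                                 stream = "gwas_effects")
    data.frame(event_id = e$event_id, trait = "GLU", beta = e$beta,
               stringsAsFactors = FALSE)
  }
  traits <- union(c("GLU", "MCH"), eff$trait)
  trait_types <- setNames(rep("quantitative", length(traits)), traits)
  trait_types["T2D"] <- "binary"
  with_substream(config$seed, "phenotypes", {
    n <- ncol(dos)
    ph <- data.frame(sample = colnames(dos),
                     age = round(rnorm(n, 50, 10), 1),
                     sex = as.integer(truth$panel$sex[
                       match(colnames(dos), truth$panel$sample)] == "F"),
                     bmi = round(rnorm(n, 24, 3), 2),
                     stringsAsFactors = FALSE)
    for (tr in names(trait_types)) {
      lp <- 0.02 * (ph$age - 50) + 0.3 * ph$sex + 0.05 * (ph$bmi - 24)
      rows <- eff[eff$trait == tr, , drop = FALSE]
      for (i in seq_len(nrow(rows)))
        lp <- lp + rows$beta[i] * dos[rows$event_id[i], ]
      if (trait_types[[tr]] == "binary") {
        ph[[tr]] <- rbinom(n, 1L, 1 / (1 + exp(-(lp - mean(lp)))))
      } else {
        ph[[tr]] <- lp + rnorm(n, 0, noise_sd)
      }
    }
    list(phenotypes = ph, effects = eff, trait_types = trait_types)
  })
}

#' Simulate a tag-SNP panel in controlled LD with planted events
#'
#' For each tagged event a SNP is placed within `max_dist` of the
#' insertion point whose haplotype alleles copy the event allele with
#' probability `sqrt(target_r2)` (so the expected dosage r-squared equals
#' the target; `target_r2 = 1` copies the genotypes exactly).  Untagged
#' SNPs are independent Bernoulli draws.  The SNP catalogue table reports
#' an association p-value: tagged SNPs are genome-wide significant
#' (p = 1e-9), untagged SNPs draw p uniformly from (0.001, 1).
#'
#' @param truth,config simulation objects; `config$snp_panel` is a list
#'   with `n_snps`, `target_r2`, `max_dist` and optionally `tags` (data
#'   frame event_id, offset, r2).
#' @return list with `genotypes` (SNPs x samples dosage matrix) and
#'   `catalogue` (snp_id, chrom, pos, p, tagged_event).
#' @export
simulate_snp_panel <- function(truth, config) {
  sp <- config$snp_panel
  ev <- truth$events
  samples <- truth$panel$sample
  tags <- sp$tags %||% {
    common <- ev$event_id[rowMeans(truth_dosage(truth)) / 2 >= 0.1]
    n_tag <- min(5L, length(common))
    with_substream(config$seed, "snp_tags", data.frame(
      event_id = sample(common, n_tag),
      offset = sample(c(-1L, 1L), n_tag, TRUE) *
        as.integer(runif(n_tag, 1000, min(50000, sp$max_dist))),
      r2 = sp$target_r2, stringsAsFactors = FALSE))
  }
  if (any(abs(tags$offset) > 100000L))
    stop("tag SNP configured more than 100 kb from its NRS")
  with_substream(config$seed, "snp_panel", {
    nsnp <- max(sp$n_snps, nrow(tags))
    geno <- matrix(0L, nsnp, length(samples),
                   dimnames = list(sprintf("SNP%05d", seq_len(nsnp)),
                                   samples))
    cat_chrom <- character(nsnp); cat_pos <- integer(nsnp)
    cat_p <- runif(nsnp, 0.001, 1)
    tagged <- rep(NA_character_, nsnp)
    # untagged SNPs: independent draws at random positions
    for (i in seq_len(nsnp)) {
      chrom <- sample(names(table(ev$chrom)), 1L)
      cat_chrom[i] <- chrom
      cat_pos[i] <- sample.int(max(ev$pos[ev$chrom == chrom]), 1L)
      af <- runif(1, 0.1, 0.5)
      geno[i, ] <- rbinom(length(samples), 1L, af) +
        rbinom(length(samples), 1L, af)
    }
    for (t in seq_len(nrow(tags))) {
      eid <- tags$event_id[t]
      ei <- match(eid, ev$event_id)
      i <- t   # first rows of the panel hold the tags
      cat_chrom[i] <- ev$chrom[ei]
      cat_pos[i] <- max(1L, ev$pos[ei] + tags$offset[t])
      cat_p[i] <- 1e-9
      tagged[i] <- eid
      cpy <- sqrt(tags$r2[t])
      afm <- mean(truth$presence[eid, , ])
      hap <- truth$presence[eid, samples, ]
      flip <- matrix(runif(length(samples) * 2) >= cpy, ncol = 2L)
      rnd <- matrix(rbinom(length(samples) * 2L, 1L, afm) == 1L, ncol = 2L)
      snp_hap <- ifelse(flip, rnd, hap)
      geno[i, ] <- as.integer(snp_hap[, 1]) + as.integer(snp_hap[, 2])
    }
    list(genotypes = geno,
         catalogue = data.frame(snp_id = rownames(geno),
                                chrom = cat_chrom, pos = cat_pos,
                                p = cat_p, tagged_event = tagged,
                                stringsAsFactors = FALSE))
  })
}
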