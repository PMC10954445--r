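#' Allele frequencies and AF categories
#'
#' Allele count is the dosage sum over included samples (trio offspring
#' excluded); allele number is twice the number of included samples with
#' a non-missing genotype.  Categories follow the population-catalogue
#' convention: singleton (allele count = 1), polymorphic (count >= 2 and
#' AF < 0.5), major (0.5 <= AF < 1), shared (AF = 1).
#'
#' @param dosage loci x samples integer matrix of 0/1/2 copies (NA =
#'   missing).
#' @param panel panel data frame (`sample`, `population`, `trio_role`).
#' @return data frame of AF records with per-population AFs.
#' @export
compute_af <- function(dosage, panel) {
  offspring <- panel$sample[panel$trio_role %in% "offspring"]
  keep <- setdiff(colnames(dosage), offspring)
  d <- dosage[, keep, drop = FALSE]
  ac <- rowSums(d, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(d))
  af <- ifelse(an > 0L, ac / an, NA_real_)
  rec <- data.frame(gnrs_id = rownames(dosage), allele_count = ac,
                    allele_number = an, af = af,
                    undefined = an == 0L, stringsAsFactors = FALSE)
  rec$category <- vapply(seq_len(nrow(rec)), function(i)
    classify_af(rec$allele_count[i], rec$af[i]), character(1))
  for (p in unique(panel$population)) {
    smp <- intersect(keep, panel$sample[panel$population == p])
    dp <- d[, smp, drop = FALSE]
    anp <- 2L * rowSums(!is.na(dp))
    rec[[paste0("af_", p)]] <- ifelse(anp > 0L,
                                      rowSums(dp, na.rm = TRUE) / anp,
                                      NA_real_)
    rec[[paste0("obs_", p)]] <- rowSums(dp > 0L, na.rm = TRUE) > 0L
  }
  rec
}

#' Classify one allele-frequency record
#'
#' @param allele_count integer allele count.
#' @param af allele frequency.
#' @return `"singleton"`, `"polymorphic"`, `"major"`, `"shared"` or `NA`
#'   when AF is undefined.
#' @export
classify_af <- function(allele_count, af) {
  if (is.na(af)) return(NA_character_)
  if (af == 1) return("shared")
  if (allele_count == 1L) return("singleton")
  if (allele_count >= 2L && af < 0.5) return("polymorphic")
  if (af >= 0.5 && af < 1) return("major")
  NA_character_
}

#' Population sharing labels
#'
#' A record is `common` when the allele is observed in every listed
#' population and `specific` when observed in exactly one; populations
#' with no sampled alleles at a locus count as unobserved, not absent.
#'
#' @param af_records output of [compute_af()].
#' @param populations populations considered.
#' @return list with per-record `label` and one-decimal summary
#'   percentages.
#' @export
population_sharing <- function(af_records,
                               populations = sub("^obs_", "",
                                 grep("^obs_", names(af_records),
                                      value = TRUE))) {
  obs <- as.matrix(af_records[, paste0("obs_", populations),
                              drop = FALSE])
  nobs <- rowSums(obs, na.rm = TRUE)
  label <- ifelse(nobs == length(populations), "common",
                  ifelse(nobs == 1L, "specific", "partial"))
  label[rowSums(!is.na(obs)) == 0L] <- NA_character_
  label <- unname(label)
  n <- sum(!is.na(label))
  list(label = label,
       summary = c(common = pct_round(sum(label == "common",
                                          na.rm = TRUE), n),
                   specific = pct_round(sum(label == "specific",
                                            na.rm = TRUE), n)))
}

#' Catalogue growth curves
#'
#' Cumulative distinct-NRS counts as samples are added: non-AFR samples
#' first (random order within the block), then AFR samples, averaged
#' over `orderings` replicates, split by AF category.
#'
#' @param sample_sets named list: per sample, the character vector of NRS
#'   ids it carries.
#' @param panel panel data frame.
#' @param categories optional named map id -> category (default: one
#'   `all` category).
#' @param orderings number of random orderings (default 10).
#' @param seed RNG seed.
#' @param afr_populations population labels treated as AFR.
#' @return data frame (n, category, mean_count).
#' @export
growth_curve <- function(sample_sets, panel, categories = NULL,
                         orderings = 10L, seed = 1L,
                         afr_populations = "AFR") {
  samples <- names(sample_sets)
  pops <- panel$population[match(samples, panel$sample)]
  is_afr <- pops %in% afr_populations
  if (is.null(categories)) {
    ids <- unique(unlist(sample_sets))
    categories <- setNames(rep("all", length(ids)), ids)
  }
  cats <- sort(unique(categories))
  acc <- array(0, dim = c(length(samples), length(cats), orderings),
               dimnames = list(NULL, cats, NULL))
  with_substream(seed, "growth_curve", {
    for (r in seq_len(orderings)) {
      ord <- c(sample(which(!is_afr)), sample(which(is_afr)))
      seen <- character(0)
      for (i in seq_along(ord)) {
        seen <- union(seen, sample_sets[[ord[i]]])
        tab <- table(factor(categories[seen], levels = cats))
        acc[i, , r] <- as.numeric(tab)
      }
    }
  })
  mean_counts <- apply(acc, c(1, 2), mean)
  data.frame(n = rep(seq_along(samples), times = length(cats)),
             category = rep(cats, each = length(samples)),
             mean_count = as.vector(mean_counts),
             stringsAsFactors = FALSE)
}

#' N50 of a length distribution
#'
#' The smallest length L such that lengths >= L sum to at least half the
#' total.
#'
#' @param lengths numeric vector of lengths.
#' @return the N50 length.
#' @export
compute_n50 <- function(lengths) {
  stopifnot(length(lengths) > 0L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Genic context of catalogue insertion points
#'
#' Deterministic precedence: coding exon > noncoding exon > intron >
#' intergenic.
#'
#' @param catalogue `nrs_catalogue` (placed records are annotated;
#'   unplaced get NA).
#' @param genes,exons annotation tables from the reference.
#' @return character vector of contexts, one per record.
#' @export
annotate_genic <- function(catalogue, genes, exons) {
  vapply(seq_len(nrow(catalogue)), function(i) {
    if (!catalogue$placed[i]) return(NA_character_)
    ch <- catalogue$chrom[i]; p <- catalogue$pos[i]
    ex <- exons[exons$chrom == ch & p >= exons$start & p < exons$end, ,
                drop = FALSE]
    if (nrow(ex) > 0L) {
      if (any(ex$type == "exon_coding")) return("exon_coding")
      return("exon_noncoding")
    }
    g <- genes[genes$chrom == ch & p >= genes$start & p < genes$end, ,
               drop = FALSE]
    if (nrow(g) > 0L) return("intron")
    "intergenic"
  }, character(1))
}

#' Fisher enrichment over annotation term sets
#'
#' One 2x2 Fisher exact test per term (hit membership x term membership
#' over the background universe), Benjamini-Hochberg corrected across
#' terms.  Empty terms are skipped and flagged.
#'
#' @param hits character vector of hit ids (subset of background).
#' @param background character vector: the universe.
#' @param term_sets named list of id vectors.
#' @return data frame (term, n_term, n_hit_term, odds_ratio, p, q,
#'   skipped).
#' @export
enrichment_fisher <- function(hits, background, term_sets) {
  hits <- intersect(hits, background)
  rows <- lapply(names(term_sets), function(tm) {
    ts <- intersect(term_sets[[tm]], background)
    if (length(ts) == 0L)
      return(data.frame(term = tm, n_term = 0L, n_hit_term = 0L,
                        odds_ratio = NA_real_, p = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    a <- length(intersect(hits, ts))
    b <- length(hits) - a
    c <- length(ts) - a
    d <- length(background) - length(hits) - c
    ft <- fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")
    data.frame(term = tm, n_term = length(ts), n_hit_term = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[!out$skipped] <- p.adjust(out$p[!out$skipped], method = "BH")
  out
}
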