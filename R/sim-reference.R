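#' Build a simulated reference genome
#'
#' Generates chromosome sequences at human-like GC (0.41), plants one
#' satellite array per chromosome (exact tandem copies of a library
#' monomer, standing in for a centromere and defining the p/q arm
#' boundary), and annotates evenly spaced genes with TSS and two exons
#' (the second exon of every fifth gene is flagged noncoding).  Also
#' carries the mobile-element library used by the event simulator and the
#' satellite monomer library used by masking filters.
#'
#' @param config [sim_config()] object.
#' @return object of class `nrs_reference` with elements `seqs` (named
#'   character), `chrom_lengths`, `arms`, `satellites`, `genes`, `exons`,
#'   `satellite_library`, `me_library`.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "nrs_sim_config"))
  L <- config$chrom_length
  ngen <- config$n_genes_per_chrom
  if (L < 50000L * max(1L, ngen %/% 10L))
    stop("chrom_length too small to host the requested annotations")
  lib <- satellite_library()
  melib <- with_substream(config$seed, "me_library", list(
    SINE_like = random_dna(300, gc = 0.47),
    LINE_like = random_dna(6000, gc = 0.42)))
  with_substream(config$seed, "reference", {
    seqs <- character(config$n_chromosomes)
    names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
    sat <- NULL; arms <- NULL; genes <- NULL; exons <- NULL
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- names(seqs)[ci]
      s <- random_dna(L, gc = 0.41)
      # centromeric satellite array in the middle 20-40 kb
      mono <- lib[[(ci - 1L) %% length(lib) + 1L]]
      ml <- nchar(mono)
      ncopy <- as.integer(round(runif(1, 20000, 40000) / ml))
      arr <- strrep(mono, ncopy)
      c0 <- as.integer(L / 2 - nchar(arr) / 2)
      s <- paste0(substr(s, 1, c0), arr,
                  substr(s, c0 + nchar(arr) + 1L, L))
      s <- substr(s, 1, L)
      c1 <- c0 + nchar(arr)
      sat <- rbind(sat, data.frame(chrom = chrom, start = c0, end = c1,
                                   monomer = names(lib)[(ci - 1L) %%
                                                        length(lib) + 1L],
                                   stringsAsFactors = FALSE))
      arms <- rbind(arms,
        data.frame(chrom = chrom, start = c(0L, c1), end = c(c0, L),
                   arm = c("p", "q"), stringsAsFactors = FALSE))
      # genes on the arms, away from the satellite
      if (ngen > 0L) {
        slots <- setdiff(seq(20000L, L - 25000L, length.out = ngen + 2L),
                         numeric(0))
        gs <- as.integer(slots[seq_len(ngen) + 1L])
        gs <- gs[gs + 20000L < c0 | gs > c1 + 2000L]
        for (gi in seq_along(gs)) {
          g0 <- gs[gi]; g1 <- g0 + 8000L
          strand <- if (gi %% 2L == 0L) "-" else "+"
          gid <- sprintf("%s_G%03d", chrom, gi)
          tss <- if (strand == "+") g0 else g1
          genes <- rbind(genes, data.frame(
            gene_id = gid, chrom = chrom, start = g0, end = g1,
            strand = strand, tss = tss, stringsAsFactors = FALSE))
          coding <- gi %% 5L != 0L
          exons <- rbind(exons, data.frame(
            gene_id = gid, chrom = chrom,
            start = c(g0, g1 - 1500L), end = c(g0 + 1500L, g1),
            type = if (coding) "exon_coding" else "exon_noncoding",
            stringsAsFactors = FALSE))
        }
      }
      seqs[chrom] <- s
    }
    structure(list(seqs = seqs,
                   chrom_lengths = setNames(rep(L, length(seqs)),
                                            names(seqs)),
                   arms = arms, satellites = sat, genes = genes,
                   exons = exons, satellite_library = lib,
                   me_library = melib),
              class = "nrs_reference")
  })
}

#' Bundled synthetic satellite monomer library
#'
#' Two fixed monomers (a 171-bp alpha-like unit and a 48-bp Hsat-like
#' unit), read from the package's plain-text resources.  They are
#' synthetic stand-ins generated once under a fixed seed, not biological
#' consensus sequences.
#'
#' @return named character vector of monomer sequences.
#' @export
satellite_library <- function() {
  path <- system.file("extdata", "satellite_library.fa", package = "nrskit")
  if (!nzchar(path)) stop("bundled satellite library not found")
  as_target_seqs(Biostrings::readDNAStringSet(path))
}
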