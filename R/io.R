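#' File formats
#'
#' Plain-text round-trip I/O for the pipeline's artefacts.  Coordinates
#' are 0-based half-open in BED and internal tables, 1-based only in
#' VCF.  Every writer accepts a `provenance` character vector serialized
#' into `##`/`#` header lines.
#'
#' @name cli_and_io
NULL

#' @rdname cli_and_io
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(nchar(s), starts + width - 1L)),
               con)
  }
  invisible(path)
}

#' @rdname cli_and_io
#' @export
read_fasta <- function(path) {
  as_target_seqs(Biostrings::readDNAStringSet(path))
}

#' @rdname cli_and_io
#' @param df data frame to write.
#' @param provenance character vector of header comments.
#' @export
write_tsv <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cli_and_io
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' @rdname cli_and_io
#' @param bed data frame with chrom/start/end (+ extra columns).
#' @export
write_bed <- function(bed, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname cli_and_io
#' @param col_names names for the BED columns.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end")) {
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[seq_along(col_names)] <- col_names
  df
}

#' Write the catalogue as VCF
#'
#' Placed records become VCF data lines: POS is the 1-based coordinate
#' of the base preceding the 0-based insertion point, REF is that base,
#' ALT is REF followed by the full insertion sequence.  INFO carries
#' GNRS, SUPP, AF (when given) and CATEGORY.  Unplaced records are not
#' representable in VCF and belong in the companion FASTA.
#'
#' @param catalogue `nrs_catalogue`.
#' @param reference reference object (for REF bases).
#' @param path output path.
#' @param af_records optional [compute_af()] output for AF/CATEGORY.
#' @param provenance header comment lines.
#' @export
write_catalogue_vcf <- function(catalogue, reference, path,
                                af_records = NULL,
                                provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=nrskit",
               paste0("##provenance=", provenance),
               "##INFO=<ID=GNRS,Number=1,Type=String,Description=\"Catalogue id\">",
               "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Supporting samples\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
               "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"AF class\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", sep = "\t")), con)
  pl <- catalogue[catalogue$placed, , drop = FALSE]
  for (i in seq_len(nrow(pl))) {
    pos0 <- pl$pos[i]
    refbase <- substr(reference$seqs[[pl$chrom[i]]], pos0, pos0)
    info <- sprintf("GNRS=%s;SUPP=%d", pl$gnrs_id[i], pl$n_supports[i])
    if (!is.null(af_records)) {
      j <- match(pl$gnrs_id[i], af_records$gnrs_id)
      if (!is.na(j))
        info <- sprintf("%s;AF=%.6g;CATEGORY=%s", info,
                        af_records$af[j], af_records$category[j])
    }
    writeLines(paste(pl$chrom[i], pos0, pl$gnrs_id[i], refbase,
                     paste0(refbase, pl$seq[i]), ".", "PASS", info,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF of insertion records
#'
#' Parses the dialect written by [write_catalogue_vcf()] (and the truth
#' VCF).  Malformed data lines raise an error naming the line number.
#'
#' @param path VCF path.
#' @return data frame (chrom, pos [0-based insertion point], id, ref,
#'   alt, info).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- gsub("\r$", "", lines)
  dat <- which(!startsWith(lines, "#"))
  rows <- lapply(dat, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed VCF line ", i, ": expected >= 8 fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF line ", i, ": bad POS")
    data.frame(chrom = f[1], pos = pos, id = f[3], ref = f[4],
               alt = f[5], info = f[8], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), info = character())
}

# Minimal flat YAML emitter for config provenance.
write_yaml_flat <- function(x, path) {
  fmt <- function(v) {
    if (is.numeric(v) || is.logical(v)) paste(v, collapse = ", ")
    else paste(as.character(v), collapse = ", ")
  }
  lines <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.data.frame(v)) next
    if (is.list(v)) {
      lines <- c(lines, paste0(nm, ":"))
      for (k in names(v))
        if (!is.data.frame(v[[k]]))
          lines <- c(lines, paste0("  ", k, ": ", fmt(v[[k]])))
    } else if (length(v) > 1L && !is.null(names(v))) {
      lines <- c(lines, paste0(nm, ":"),
                 paste0("  ", names(v), ": ", unname(v)))
    } else {
      lines <- c(lines, paste0(nm, ": ", fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the simulated world to disk
#'
#' Reference FASTA (+ .fai), satellite/gene/TSS BED tracks, panel TSV,
#' truth VCF (ALT = full inserted sequence; INFO CLASS and EVENT_ID),
#' per-sample contig FASTA and depth BED, and the config as flat YAML.
#'
#' @param ref,truth,config,assemblies simulation objects (`assemblies`
#'   optional).
#' @param dir output directory (created).
#' @export
write_simulation <- function(ref, truth, config, dir,
                             assemblies = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  write_fasta(ref$seqs, fa)
  fai <- data.frame(name = names(ref$seqs),
                    length = nchar(ref$seqs),
                    offset = cumsum(c(0, head(nchar(names(ref$seqs)) + 2 +
                      nchar(ref$seqs) + ceiling(nchar(ref$seqs) / 70),
                      -1))) + nchar(names(ref$seqs)) + 2,
                    linebases = 70L, linewidth = 71L)
  write.table(fai, paste0(fa, ".fai"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(ref$satellites, file.path(dir, "satellites.bed"))
  write_bed(ref$genes[, c("chrom", "start", "end", "gene_id", "tss",
                          "strand")], file.path(dir, "genes.bed"))
  write_tsv(truth$panel, file.path(dir, "panel.tsv"))
  con <- file(file.path(dir, "truth.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2", "##source=nrskit-sim",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Event class\">",
               "##INFO=<ID=EVENT_ID,Number=1,Type=String,Description=\"Truth id\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", sep = "\t")), con)
  ev <- truth$events
  for (i in seq_len(nrow(ev))) {
    refbase <- substr(ref$seqs[[ev$chrom[i]]], ev$pos[i], ev$pos[i])
    writeLines(paste(ev$chrom[i], ev$pos[i], ev$event_id[i], refbase,
                     paste0(refbase, ev$seq[i]), ".", "PASS",
                     sprintf("CLASS=%s;EVENT_ID=%s", ev$class[i],
                             ev$event_id[i]), sep = "\t"), con)
  }
  close(con)
  if (!is.null(assemblies)) {
    ad <- file.path(dir, "assemblies")
    dir.create(ad, showWarnings = FALSE)
    for (smp in names(assemblies$samples)) {
      write_fasta(assemblies$samples[[smp]]$contigs,
                  file.path(ad, paste0(smp, ".fa")))
      write_bed(assemblies$samples[[smp]]$depth,
                file.path(ad, paste0(smp, ".depth.bed")))
    }
  }
  write_yaml_flat(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}
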