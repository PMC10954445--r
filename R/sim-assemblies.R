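#' Emit per-sample assemblies with planted events
#'
#' Builds two haplotype sequences per chromosome per sample (reference
#' with the sample's events spliced in), fragments them with a Poisson
#' breakpoint process, appends contaminant contigs drawn from a distinct
#' composition model, and attaches a per-contig depth track.  A small
#' fraction of event-carrying contigs is given 3.5x depth as bait for the
#' depth filter.  Truth labels record, per (event, sample), whether at
#' least one copy is anchorable (>= 1 kb of intact flank on both sides
#' inside one clean contig).
#'
#' @param ref,truth,config simulation objects.
#' @param samples optional subset of sample ids (default: whole panel).
#' @return list with `samples` (named list of `contigs`/`depth` per
#'   sample) and `labels` (`anchorable` event x sample matrix,
#'   `contaminant_contigs`, `depth_bait` data frame).
#' @export
emit_assemblies <- function(ref, truth, config,
                            samples = truth$panel$sample) {
  stopifnot(inherits(truth, "nrs_truth"))
  ev <- truth$events
  nev <- nrow(ev)
  anchorable <- matrix(FALSE, nev, length(samples),
                       dimnames = list(ev$event_id, samples))
  contam_ids <- character(0)
  bait <- NULL
  out <- vector("list", length(samples))
  names(out) <- samples
  for (smp in samples) {
    res <- with_substream(config$seed, paste0("assembly_", smp), {
      contigs <- character(0); depth <- NULL
      anchor_ok <- rep(FALSE, nev)
      carries_any <- FALSE
      for (hap in 1:2) {
        for (chrom in names(ref$seqs)) {
          idx <- which(ev$chrom == chrom & truth$presence[, smp, hap])
          hapseq <- splice_events(ref$seqs[[chrom]],
                                  ev$pos[idx], ev$seq[idx])
          evpos <- spliced_positions(ev$pos[idx], nchar(ev$seq[idx]))
          n <- nchar(hapseq)
          nb <- rpois(1L, config$fragment_rate * n)
          brk <- sort(sample(n - 1L, min(nb, n - 1L)))
          bounds <- c(0L, brk, n)
          for (ci in seq_len(length(bounds) - 1L)) {
            b0 <- bounds[ci]; b1 <- bounds[ci + 1L]
            if (b1 - b0 < 200L) next
            cid <- sprintf("%s_%s_h%d_c%02d", smp, chrom, hap, ci)
            cseq <- substr(hapseq, b0 + 1L, b1)
            inside <- idx[evpos$start >= b0 & evpos$end <= b1]
            ok <- idx[evpos$start - 1000L >= b0 & evpos$end + 1000L <= b1]
            d <- rnorm(1, config$depth_mean, 0.05 * config$depth_mean)
            if (length(inside) > 0L &&
                runif(1) < config$depth_bait_fraction) {
              d <- 3.5 * config$depth_mean
              bait <- rbind(bait, data.frame(
                sample = smp, contig = cid,
                event_id = ev$event_id[inside],
                stringsAsFactors = FALSE))
            } else if (length(ok) > 0L) {
              anchor_ok[ok] <- TRUE
            }
            contigs[cid] <- cseq
            depth <- rbind(depth, data.frame(
              contig = cid, start = 0L, end = b1 - b0, depth = d,
              stringsAsFactors = FALSE))
          }
        }
      }
      ncont <- round(config$contaminant_fraction * length(contigs))
      if (ncont > 0L) for (k in seq_len(ncont)) {
        cid <- sprintf("%s_ctg_x%02d", smp, k)
        contigs[cid] <- foreign_dna(as.integer(runif(1, 1500, 8000)))
        depth <- rbind(depth, data.frame(
          contig = cid, start = 0L, end = nchar(contigs[cid]),
          depth = rnorm(1, config$depth_mean, 0.05 * config$depth_mean),
          stringsAsFactors = FALSE))
        contam_ids <- c(contam_ids, cid)
      }
      list(contigs = contigs, depth = depth, anchor_ok = anchor_ok)
    })
    anchorable[, smp] <- res$anchor_ok
    out[[smp]] <- list(contigs = res$contigs, depth = res$depth)
  }
  list(samples = out,
       labels = list(anchorable = anchorable,
                     contaminant_contigs = contam_ids,
                     depth_bait = bait))
}

# Splice event sequences into a chromosome (positions are 0-based
# between-base insertion points on the reference coordinate).
splice_events <- function(refseq, pos, seqs) {
  if (length(pos) == 0L) return(refseq)
  ord <- order(pos, decreasing = TRUE)
  s <- refseq
  for (i in ord)
    s <- paste0(substr(s, 1L, pos[i]), seqs[i],
                substr(s, pos[i] + 1L, nchar(s)))
  s
}

# Haplotype-coordinate spans of spliced events (0-based half-open).
spliced_positions <- function(pos, lens) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ord <- order(pos)
  shift <- c(0L, cumsum(lens[ord]))[seq_along(pos)]
  start <- pos[ord] + shift
  data.frame(start = start, end = start + lens[ord])[order(ord), ,
                                                     drop = FALSE]
}

#' Contaminant sequence generator
#'
#' First-order Markov chain with GC-shifted, motif-biased transitions --
#' a composition clearly distinct from the host model without bundling
#' any real microbial genome.
#'
#' @param n sequence length.
#' @return character scalar.
#' @export
foreign_dna <- function(n) {
  bases <- c("A", "C", "G", "T")
  trans <- rbind(A = c(0.15, 0.35, 0.35, 0.15),
                 C = c(0.10, 0.30, 0.45, 0.15),
                 G = c(0.15, 0.45, 0.30, 0.10),
                 T = c(0.15, 0.35, 0.35, 0.15))
  out <- character(n)
  cur <- sample(4L, 1L)
  out[1] <- bases[cur]
  u <- runif(n)
  for (i in seq_len(n - 1L)) {
    cur <- findInterval(u[i], cumsum(trans[cur, ])) + 1L
    out[i + 1L] <- bases[cur]
  }
  paste(out, collapse = "")
}

#' Default composition profiles for contamination screening
#'
#' The host profile is estimated from the reference sequences at hand;
#' the foreign profile is read from the bundled resource (estimated once
#' from the [foreign_dna()] model).
#'
#' @param ref reference object (or any sequence set) for the host profile.
#' @return list with `host` and `foreign` profiles.
#' @export
composition_profiles <- function(ref) {
  host <- make_composition_profile(as_target_seqs(ref), label = "host")
  path <- system.file("extdata", "foreign_profile.tsv", package = "nrskit")
  tb <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  foreign <- structure(list(label = "foreign",
                            tetra = setNames(tb$freq, tb$tetramer),
                            gc = attr_num(tb)),
                       class = "nrs_composition_profile")
  list(host = host, foreign = foreign)
}

attr_num <- function(tb) tb$gc[1]
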