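#' Simulate a population carrying the planted events
#'
#' Draws diploid presence of every planted event for every sample from the
#' event's per-population allele frequency, builds the sample panel
#' (population, platform, sex, trio structure) and generates the event
#' sequences.  Trio offspring inherit one haplotype from each parent, so
#' simulated trios are Mendelian-consistent by construction.
#'
#' @param ref [build_reference()] output.
#' @param config [sim_config()] object.
#' @return object of class `nrs_truth`: `events` (data frame with
#'   sequences and 0-based insertion points), `presence` (events x samples
#'   x 2 logical array), `panel`, `pedigree`, `selection` (event ids),
#'   `genes` (TSS table copied from the reference).
#' @export
simulate_population <- function(ref, config) {
  stopifnot(inherits(ref, "nrs_reference"), inherits(config, "nrs_sim_config"))
  pops <- names(config$n_samples_per_population)
  panel <- do.call(rbind, lapply(pops, function(p) {
    n <- config$n_samples_per_population[[p]]
    data.frame(sample = sprintf("%s%03d", p, seq_len(n)), population = p,
               platform = rep_len(config$platform_levels, n),
               sex = rep_len(c("M", "F"), n), trio_id = NA_character_,
               trio_role = NA_character_, stringsAsFactors = FALSE)
  }))
  pedigree <- NULL
  if (config$n_trios > 0L) for (t in seq_len(config$n_trios)) {
    p <- pops[(t - 1L) %% length(pops) + 1L]
    idx <- which(panel$population == p & is.na(panel$trio_role))[1:2]
    if (any(is.na(idx))) stop("not enough samples in ", p, " for a trio")
    tid <- sprintf("TRIO%d", t)
    panel$trio_id[idx] <- tid
    panel$trio_role[idx] <- c("father", "mother")
    child <- sprintf("%sC%02d", p, t)
    panel <- rbind(panel, data.frame(
      sample = child, population = p,
      platform = panel$platform[idx[1]], sex = "F", trio_id = tid,
      trio_role = "offspring", stringsAsFactors = FALSE))
    pedigree <- rbind(pedigree, data.frame(
      child = child, father = panel$sample[idx[1]],
      mother = panel$sample[idx[2]], stringsAsFactors = FALSE))
  }
  ev <- config$nrs_event_table
  ev$seq <- with_substream(config$seed, "event_seqs",
                           make_event_seqs(ev, ref))
  ev$length <- nchar(ev$seq)
  pos <- with_substream(config$seed, "event_positions",
                        place_events(nrow(ev), ref))
  ev$chrom <- pos$chrom
  ev$pos <- pos$pos
  ev <- ev[order(match(ev$chrom, names(ref$seqs)), ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  presence <- with_substream(config$seed, "presence", {
    arr <- array(FALSE, dim = c(nrow(ev), nrow(panel), 2L),
                 dimnames = list(ev$event_id, panel$sample, NULL))
    for (p in pops) {
      af <- ev[[paste0("af_", p)]]
      smp <- panel$sample[panel$population == p &
                          !(panel$trio_role %in% "offspring")]
      for (s in smp)
        arr[, s, ] <- matrix(rbinom(2L * nrow(ev), 1L, af), ncol = 2L) == 1L
    }
    if (!is.null(pedigree)) for (i in seq_len(nrow(pedigree))) {
      fa <- pedigree$father[i]; mo <- pedigree$mother[i]
      ch <- pedigree$child[i]
      pick_f <- sample(1:2, nrow(ev), replace = TRUE)
      pick_m <- sample(1:2, nrow(ev), replace = TRUE)
      arr[, ch, 1L] <- arr[, fa, ][cbind(seq_len(nrow(ev)), pick_f)]
      arr[, ch, 2L] <- arr[, mo, ][cbind(seq_len(nrow(ev)), pick_m)]
    }
    arr
  })
  structure(list(events = ev, presence = presence, panel = panel,
                 pedigree = pedigree,
                 selection = ev$event_id[ev$selection],
                 genes = ref$genes),
            class = "nrs_truth")
}

# Event sequence constructors (caller provides the RNG substream).
make_event_seqs <- function(ev, ref) {
  vapply(seq_len(nrow(ev)), function(i) {
    len <- ev$length[i]
    switch(ev$class[i],
      tandem_repeat = {
        ml <- sample(2:min(100L, max(2L, len %/% 5L)), 1L)
        motif <- random_dna(ml, gc = 0.41)
        strrep(motif, max(5L, ceiling(len / ml)))
      },
      mobile_element_like = {
        src <- if (len <= 300L) ref$me_library$SINE_like else
          ref$me_library$LINE_like
        off <- sample(max(1L, nchar(src) - len), 1L)
        mutate_seq(substr(src, off, min(nchar(src), off + len - 1L)),
                   runif(1, 0.01, 0.05))
      },
      unique_novel = random_dna(len, gc = 0.41),
      stop("unknown event class: ", ev$class[i]))
  }, character(1))
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# Insertion points: uniform over grid slots spaced 3 kb, excluding the
# satellite array (+/- 2 kb) and 2 kb chromosome-end margins so every
# event has room for intact flanks.
place_events <- function(n, ref) {
  slots <- do.call(rbind, lapply(names(ref$seqs), function(chrom) {
    L <- ref$chrom_lengths[[chrom]]
    sat <- ref$satellites[ref$satellites$chrom == chrom, , drop = FALSE]
    cand <- seq(2000L, L - 2000L, by = 3000L)
    for (i in seq_len(nrow(sat)))
      cand <- cand[cand < sat$start[i] - 2000L | cand > sat$end[i] + 2000L]
    data.frame(chrom = chrom, pos = cand, stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n)
    stop("chrom_length too small to place ", n, " events")
  picked <- slots[sample(nrow(slots), n), , drop = FALSE]
  # jitter within the slot, keeping 1 kb clearance
  picked$pos <- as.integer(picked$pos + sample(0:999, n, replace = TRUE))
  rownames(picked) <- NULL
  picked
}

#' Truth diploid dosage matrix (events x samples)
#'
#' @param truth `nrs_truth` object.
#' @return integer matrix of 0/1/2 copies.
#' @export
truth_dosage <- function(truth) {
  d <- truth$presence[, , 1L] + truth$presence[, , 2L]
  mode(d) <- "integer"
  d
}
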