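mk_calls <- function(pos, sample = paste0("s", seq_along(pos)),
                     seq = "ACGTACGTAC", chrom = "chr1") {
  data.frame(sample = sample, contig = "c", seq = seq, chrom = chrom,
             pos = as.integer(pos), strand = "+", up_len = 1000L,
             down_len = 1000L, gap = 0L, stringsAsFactors = FALSE)
}

test_that("cluster_placed honours the 250 bp pairwise bound", {
  cl <- cluster_placed(mk_calls(c(100, 220)))
  expect_length(cl, 1L)

  cl2 <- cluster_placed(mk_calls(c(100, 500)))
  expect_length(cl2, 2L)

  # three calls at 0/200/400: split so that no pair exceeds 250
  cl3 <- cluster_placed(mk_calls(c(0, 200, 400)))
  expect_length(cl3, 2L)
  sizes <- sort(vapply(cl3, function(x) nrow(x$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
  expect_equal(sort(cl3[[1]]$members$pos), c(0L, 200L))
  expect_equal(cl3[[2]]$members$pos, 400L)
})

test_that("cluster splitting matches the brute-force optimum on small inputs", {
  set.seed(17)
  for (case in 1:40) {
    n <- sample(2:6, 1)
    pos <- sort(sample.int(1200, n))
    cl <- cluster_placed(mk_calls(pos))
    # every cluster respects the diameter bound
    for (c_ in cl)
      expect_lte(max(c_$members$pos) - min(c_$members$pos), 250)
    # and the number of clusters is optimal
    expect_equal(length(cl), min_clusters_oracle(pos, 250))
  }
})

test_that("one member per sample is kept, closest to the median", {
  calls <- mk_calls(c(100, 140, 120), sample = c("s1", "s1", "s2"))
  cl <- cluster_placed(calls)
  expect_length(cl, 1L)
  m <- cl[[1]]$members
  expect_equal(nrow(m), 2L)
  expect_equal(m$pos[m$sample == "s1"], 100L)  # 100 is closer to median 120
})

test_that("select_representatives: singleton, identical and divergent clusters", {
  cl <- cluster_placed(mk_calls(100))
  rec <- select_representatives(cl)
  expect_equal(rec$seq, "ACGTACGTAC")
  expect_equal(rec$n_supports, 1L)

  ten <- cluster_placed(mk_calls(rep(100, 10) + 0:9,
                                 sample = paste0("s", 1:10)))
  rec10 <- select_representatives(ten)
  expect_equal(rec10$seq, "ACGTACGTAC")
  expect_equal(rec10$n_supports, 10L)
  expect_equal(rec10$pos, floor(median(100:109)))
  expect_false(rec10$multi_allelic)

  set.seed(3)
  div <- cluster_placed(mk_calls(c(100, 110),
                                 seq = c(random_dna_test(300),
                                         random_dna_test(300))))
  expect_true(select_representatives(div)$multi_allelic)
})

test_that("merge_unplaced: containment, singletons and shared sequence", {
  set.seed(23)
  B <- random_dna_test(600)
  A <- substr(B, 100, 500)   # A contained in B
  calls <- data.frame(sample = c("s1", "s2"), contig = "c",
                      seq = c(A, B), reason = "x",
                      stringsAsFactors = FALSE)
  out <- merge_unplaced(calls)
  expect_equal(out$seq, B)   # the shorter contained sequence is removed
  expect_equal(out$n_supports, 2L)

  # two unrelated singleton-sample sequences are both dropped
  lone <- data.frame(sample = c("s1", "s2"), contig = "c",
                     seq = c(random_dna_test(400), random_dna_test(400)),
                     reason = "x", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_unplaced(lone)), 0L)

  shared <- data.frame(sample = c("s1", "s2", "s3"), contig = "c",
                       seq = random_dna_test(400), reason = "x",
                       stringsAsFactors = FALSE)
  ms <- merge_unplaced(shared)
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$n_supports, 3L)
})

test_that("catalogue ids are stable and merging is idempotent", {
  set.seed(29)
  calls <- mk_calls(c(1000, 5000, 9000, 9100),
                    sample = c("s1", "s2", "s3", "s4"),
                    seq = random_dna_test(200))
  cat1 <- build_catalogue(select_representatives(cluster_placed(calls)))
  expect_equal(cat1$gnrs_id, paste0("GNRS_", seq_len(nrow(cat1))))
  expect_false(is.unsorted(cat1$pos[cat1$placed]))
  # re-merging the catalogue's own records yields the same record count
  again <- mk_calls(cat1$pos, sample = paste0("r", seq_len(nrow(cat1))),
                    seq = cat1$seq)
  cat2 <- build_catalogue(select_representatives(cluster_placed(again)))
  expect_equal(nrow(cat2), nrow(cat1))
  expect_equal(cat2$pos, cat1$pos)
})

test_that("cluster membership is invariant to sample order", {
  set.seed(37)
  pos <- sort(sample.int(50000, 25))
  calls <- mk_calls(pos, sample = paste0("s", seq_along(pos)))
  base <- cluster_placed(calls)
  base_sizes <- sort(vapply(base, function(x) nrow(x$members), integer(1)))
  for (r in 1:10) {
    sh <- calls[sample(nrow(calls)), , drop = FALSE]
    cl <- cluster_placed(sh)
    expect_equal(sort(vapply(cl, function(x) nrow(x$members),
                             integer(1))), base_sizes)
  }
})

test_that("compare_catalogues applies the 200 bp / 90% / 80% rule", {
  set.seed(41)
  seqs <- vapply(1:6, function(i) random_dna_test(400), character(1))
  recs <- data.frame(chrom = "chr1", pos = 1:6 * 1000L, seq = seqs,
                     rep_sample = "s", tie_break = "score",
                     n_supports = 2L, supports = "s1,s2",
                     multi_allelic = FALSE, stringsAsFactors = FALSE)
  cat_ <- build_catalogue(recs)

  self <- compare_catalogues(cat_, setNames(cat_$seq, cat_$gnrs_id))
  expect_equal(self$fraction, 1)

  # external copies at ~85% identity never qualify
  deg <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    for (i in sample(400, 60))
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1))
  expect_equal(compare_catalogues(cat_, setNames(deg, paste0("d", 1:6)))$
                 n_recovered, 0L)

  half <- compare_catalogues(cat_, setNames(seqs[1:3], paste0("h", 1:3)))
  expect_equal(half$fraction, 0.5)
})
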