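test_that("align_pair recovers exact, reverse-complement and mutated slices", {
  set.seed(42)
  tgt <- c(ref = random_dna_test(40000))
  idx <- build_target_index(tgt)
  q <- substr(tgt[["ref"]], 8001, 9000)

  a <- align_pair(q, idx)
  expect_equal(nrow(a), 1L)
  expect_equal(a$identity, 1)
  expect_equal(a$coverage, 1)
  expect_equal(c(a$tstart, a$tend), c(8000L, 9000L))

  rc <- align_pair(nrskit:::revcomp(q), idx)
  expect_equal(rc$strand[1], "-")
  expect_equal(rc$identity[1], 1)
  expect_equal(rc$score[1], a$score[1])   # strand symmetry

  # 5% seeded substitutions: identity within 0.02 of the planted rate
  ch <- strsplit(q, "")[[1]]
  mut <- sample(1000, 50)
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  am <- align_pair(paste(ch, collapse = ""), idx)
  expect_lt(abs(am$identity[1] - 0.95), 0.02)
})

test_that("align_pair input contract", {
  idx <- build_target_index(c(ref = strrep("ACGT", 100)))
  expect_error(align_pair("", idx), "empty")
  expect_error(align_pair("ACGTX", idx), "non-ACGTN")
  expect_equal(nrow(align_pair(strrep("N", 100), idx)), 0L)
})

test_that("self-alignment is perfect for a panel of seeded queries", {
  set.seed(7)
  for (n in c(120, 1000, 5000)) {
    s <- c(x = random_dna_test(n))
    a <- align_pair(s[["x"]], build_target_index(s))
    expect_equal(a$identity[1], 1)
    expect_equal(a$coverage[1], 1)
  }
})

test_that("scan_tandem_repeats: worked examples", {
  tr <- scan_tandem_repeats(strrep("ACG", 50))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$motif, "ACG")
  expect_equal(tr$copies, 50)
  expect_equal(tr$class, "STR")

  # a 678-copy CTG expansion is recovered with copy number 678 +/- 1
  big <- scan_tandem_repeats(strrep("CTG", 678))
  expect_equal(big$class[1], "STR")
  expect_lte(abs(big$copies[1] - 678), 1)

  set.seed(5)
  s <- random_dna_test(1000)
  ann <- scan_tandem_repeats(s)
  expect_lt(mask_and_fraction(s, ann)$fraction, 0.2)
  # every reported array truly has >= 80% unit agreement (direct check)
  for (i in seq_len(nrow(ann))) {
    sub <- substr(s, ann$start[i] + 1, ann$end[i])
    p <- nchar(ann$motif[i])
    cc <- strsplit(sub, "")[[1]]
    agree <- mean(cc[seq_len(length(cc) - p)] == cc[-seq_len(p)])
    expect_gte(agree, 0.8)
  }
})

test_that("scan_tandem_repeats exactly recovers motif and copy number on a grid", {
  set.seed(31)
  for (ml in c(1L, 2L, 3L, 5L, 8L, 13L, 24L)) {
    for (k in c(5L, 17L, 101L, 500L)) {
      motif <- random_primitive_motif(ml)
      ann <- scan_tandem_repeats(strrep(motif, k))
      expect_equal(nrow(ann), 1L,
                   info = sprintf("motif %s x %d", motif, k))
      expect_equal(ann$motif, nrskit:::canonical_rotation(motif))
      expect_equal(ann$copies, k)
    }
  }
})

test_that("mask_and_fraction computes interval unions", {
  expect_equal(mask_and_fraction("ACGTACGT",
                                 nrskit:::repeat_annotation())$fraction, 0)
  s <- strrep("A", 100)
  full <- nrskit:::repeat_annotation(0, 100, "STR", "A", 100)
  expect_equal(mask_and_fraction(s, full)$fraction, 1)
  # overlapping intervals are unioned: [0,60) u [40,80) covers 80 bp
  two <- nrskit:::repeat_annotation(c(0, 40), c(60, 80), c("STR", "STR"),
                                    c("A", "A"), c(1, 1))
  r <- mask_and_fraction(s, two)
  expect_equal(r$fraction, 0.8)
  expect_equal(substr(r$masked, 1, 1), "N")
  # [0,60) u [40,100) covers the whole sequence
  whole <- nrskit:::repeat_annotation(c(0, 40), c(60, 100),
                                      c("STR", "STR"), c("A", "A"),
                                      c(1, 1))
  expect_equal(mask_and_fraction(s, whole)$fraction, 1)
})

test_that("match_satellites finds library arrays", {
  lib <- satellite_library()
  mono <- lib[[1]]
  arr <- strrep(mono, 40)
  ann <- match_satellites(arr, lib)
  expect_equal(nrow(ann), 1L)
  expect_gte(ann$end - ann$start, 0.98 * nchar(arr))

  set.seed(3)
  expect_equal(nrow(match_satellites(random_dna_test(2000), lib)), 0L)

  half <- paste0(strrep(mono, 20), random_dna_test(20 * nchar(mono)))
  f <- mask_and_fraction(half, match_satellites(half, lib))$fraction
  expect_lt(abs(f - 0.5), nchar(mono) / nchar(half) + 0.02)
})

test_that("classify_taxon separates host, foreign and chimeric composition", {
  set.seed(12)
  host_seqs <- replicate(10, random_dna_test(3000, gc = 0.41))
  host <- make_composition_profile(host_seqs, "host")
  foreign_seqs <- replicate(10, foreign_dna(3000))
  foreign <- make_composition_profile(foreign_seqs, "foreign")

  expect_equal(classify_taxon(random_dna_test(1000, gc = 0.41),
                              host, foreign)$value, "chordate")
  expect_equal(classify_taxon(foreign_dna(1000), host, foreign)$value,
               "non_chordate")
  chimera <- paste0(random_dna_test(500, gc = 0.41), foreign_dna(500))
  expect_equal(classify_taxon(chimera, host, foreign)$value,
               "unclassified")
  expect_equal(classify_taxon("ACGT", host, foreign)$value,
               "unclassified")  # below the profile window
})

test_that("choose_representative: worked examples and tie-breaks", {
  one <- choose_representative("ACGT")
  expect_equal(one$representative, "ACGT")
  expect_equal(one$scores, 0)

  r <- choose_representative(c("ACGTACGT", "ACGTACGT", "ACGTACGA"))
  expect_equal(r$representative, "ACGTACGT")
  expect_equal(r$scores, c(29, 29, 26))

  same <- choose_representative(rep("TTAAGG", 4))
  expect_equal(same$index, 1L)
  expect_error(choose_representative(character(0)), "at least one")
})

test_that("choose_representative agrees with brute-force pairwise scoring", {
  set.seed(88)
  for (case in 1:25) {
    n <- sample(2:5, 1)
    seqs <- vapply(seq_len(n), function(i)
      random_dna_test(sample(3:12, 1)), character(1))
    got <- choose_representative(seqs)
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      S[i, j] <- nw_score_oracle(seqs[i], seqs[j])
    totals <- rowSums(S)
    expect_equal(got$scores, totals, tolerance = 1e-9)
    expect_equal(got$scores[got$index], max(totals))
  }
})
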