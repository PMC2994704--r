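# Overlap-probability PFM similarity: calibration, joint probabilities,
# Smax and its axioms, checked against whole-window enumeration oracles.

test_that("hit-model calibration matches dinucleotide enumeration", {
  ac <- iupac_to_pfm("AC", id = "AC")
  hm <- calibrate_hit_model(ac, alpha = 0.1)
  expect_equal(hm$p, 1 / 16)  # exactly the word AC among 16 dinucleotides
  expect_equal(oracle_hit_prob(hm), 1 / 16)
})

test_that("degenerate all-uniform PFM yields p = 1 with a warning", {
  u <- pfm(matrix(1, 4, 3), id = "uni")
  expect_warning(hm <- calibrate_hit_model(u, alpha = 0.5), "best word")
  expect_equal(hm$p, 1)
})

test_that("alpha outside (0,1) is rejected", {
  expect_error(calibrate_hit_model(random_pfm(2), alpha = 0), "alpha")
  expect_error(calibrate_hit_model(random_pfm(2), alpha = 1), "alpha")
})

test_that("DP hit probability equals enumeration for random short PFMs", {
  set.seed(42)
  for (i in 1:20) {
    hm <- suppressWarnings(calibrate_hit_model(random_pfm(sample(1:3, 1)), alpha = 0.2))
    expect_equal(hm$p, oracle_hit_prob(hm), tolerance = 1e-12)
  }
})

test_that("joint overlap probability matches enumeration oracle", {
  ac <- calibrate_hit_model(iupac_to_pfm("AC", id = "AC"), alpha = 0.1)
  expect_equal(overlap_probability(ac, ac, 0), 1 / 16)
  aa <- suppressWarnings(calibrate_hit_model(iupac_to_pfm("AA", id = "AA"), alpha = 0.1))
  cc <- suppressWarnings(calibrate_hit_model(iupac_to_pfm("CC", id = "CC"), alpha = 0.1))
  for (s in -1:1) expect_equal(overlap_probability(aa, cc, s), 0)
  expect_error(overlap_probability(ac, ac, 5), "outside")
  set.seed(7)
  for (i in 1:15) {
    hA <- suppressWarnings(calibrate_hit_model(random_pfm(sample(2:3, 1)), alpha = 0.2))
    hB <- suppressWarnings(calibrate_hit_model(random_pfm(sample(2:3, 1)), alpha = 0.2))
    for (orient in c("sense", "antisense")) {
      s <- sample(seq(-(ncol(hB$scores) - 1L), ncol(hA$scores) - 1L), 1)
      expect_equal(overlap_probability(hA, hB, s, orient),
                   oracle_gamma(hA, hB, s, orient), tolerance = 1e-9)
      expect_equal(overlap_probability(hA, hB, s, orient, method = "enumerate"),
                   oracle_gamma(hA, hB, s, orient), tolerance = 1e-9)
    }
  }
})

test_that("self-similarity is exact and the distance transform holds", {
  set.seed(9)
  for (L in c(2, 5, 8)) {
    p <- random_pfm(L)
    s <- suppressWarnings(smax(p, p, alpha = 0.05))
    expect_equal(s$s_norm, 1, tolerance = 1e-9)
    expect_equal(s$d, 0, tolerance = 1e-9)
    expect_equal(s$smax_raw, 1 / s$p_A, tolerance = 1e-9)
  }
  # transform consistency: s_norm and d always sum to 1
  s <- suppressWarnings(smax(random_pfm(4), random_pfm(5), alpha = 0.05))
  expect_equal(s$s_norm + s$d, 1)
})

test_that("reverse-complement pairs are recognized through the antisense orientation", {
  ac <- iupac_to_pfm("AC", id = "AC")
  gt <- iupac_to_pfm("GT", id = "GT")  # GT = revcomp(AC)
  s <- smax(ac, gt, alpha = 0.1)
  expect_equal(s$s_norm, 1, tolerance = 1e-9)
  expect_equal(s$best_orientation, "antisense")
  expect_equal(s$best_offset, 0L)
})

test_that("similarity axioms hold on random pairs", {
  set.seed(13)
  for (i in 1:12) {
    a <- random_pfm(sample(2:3, 1))
    b <- random_pfm(sample(2:3, 1))
    sab <- suppressWarnings(smax(a, b, alpha = 0.2))
    sba <- suppressWarnings(smax(b, a, alpha = 0.2))
    expect_equal(sab$s_norm, sba$s_norm, tolerance = 1e-9)
    src <- suppressWarnings(smax(pfm_revcomp(a), pfm_revcomp(b), alpha = 0.2))
    expect_equal(sab$s_norm, src$s_norm, tolerance = 1e-9)
    expect_gte(sab$s_norm, 0)
    expect_lte(sab$s_norm, 1)
    expect_equal(sab$s_norm, suppressWarnings(oracle_s_norm(
      calibrate_hit_model(a, alpha = 0.2),
      calibrate_hit_model(b, alpha = 0.2))), tolerance = 1e-9)
  }
})

test_that("grid DP agrees with exact convolution on longer motifs", {
  set.seed(21)
  p <- random_pfm(7)
  exact <- calibrate_hit_model(p, alpha = 0.05, exact_cap = 8L)
  grid <- calibrate_hit_model(p, alpha = 0.05, exact_cap = 0L, step = 1e-4)
  expect_equal(grid$p, exact$p, tolerance = 1e-4)
  expect_equal(grid$threshold, exact$threshold, tolerance = 1e-2)
})

test_that("similarity matrix is symmetric with unit diagonal", {
  set.seed(31)
  pfms <- lapply(c(3, 4, 5), random_pfm)
  S <- pfm_similarity_matrix(pfms, alpha = 0.1)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
})
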