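# Weight-score promoter scanner and cutoff calibration.

test_that("PFM to weight-matrix conversion follows the smoothed log2 ratio", {
  bgpfm <- pfm(matrix(0.25, 4, 3), id = "bg")
  pw <- pfm_to_scoring_pwm(bgpfm, pseudocount = 0.01)
  expect_equal(unname(pw$matrix), matrix(0, 4, 3))
  half <- pfm(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1), id = "h")
  pw0 <- pfm_to_scoring_pwm(half, pseudocount = 0)
  expect_equal(unname(pw0$matrix[1, 1]), 1)      # log2(0.5/0.25)
  det <- iupac_to_pfm("AC", id = "AC")
  pwd <- pfm_to_scoring_pwm(det, pseudocount = 0.01)
  expect_true(all(is.finite(pwd$matrix)))
  expect_true(all(pwd$matrix[2:4, 1] < 0))
  expect_error(pfm_to_scoring_pwm(det, pseudocount = 0), "zero frequency")
})

test_that("weight scores match the closed-form per-position sum", {
  det <- iupac_to_pfm("AC", id = "AC")
  pw <- pfm_to_scoring_pwm(det, pseudocount = 0.01)
  expected <- 2 * log2(((1 + 0.01 * 0.25) / 1.01) / 0.25)
  expect_equal(weight_score(pw, "AC"), expected, tolerance = 1e-12)
  bgpfm <- pfm(matrix(0.25, 4, 4), id = "bg")
  pwu <- pfm_to_scoring_pwm(bgpfm)
  for (w in c("ACGT", "TTTT", "GATC")) expect_equal(weight_score(pwu, w), 0)
  # random windows against a direct per-position oracle
  set.seed(601)
  p <- random_pfm(5)
  pw2 <- pfm_to_scoring_pwm(p)
  for (i in 1:10) {
    w <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    oracle <- sum(vapply(1:5, function(j) pw2$matrix[idx[j], j], numeric(1)))
    expect_equal(weight_score(pw2, w), oracle, tolerance = 1e-12)
  }
  expect_error(weight_score(pw2, "ACG"), "length")
})

test_that("cutoff calibration minimizes false positives exactly (order 0)", {
  det <- iupac_to_pfm("AC", id = "AC")
  pw <- pfm_to_scoring_pwm(det, pseudocount = 0.01)
  cal <- calibrate_cutoff(pw, alpha = 0.1)
  expect_equal(cal$hit_prob, 1 / 16)     # exactly the word AC
  expect_equal(cal$cutoff, weight_score(pw, "AC"), tolerance = 1e-9)
  cal_all <- calibrate_cutoff(pw, alpha = 1)
  expect_equal(cal_all$hit_prob, 1)      # min achievable score admits all
  set.seed(602)
  p <- random_pfm(4)
  pwr <- pfm_to_scoring_pwm(p)
  cal2 <- calibrate_cutoff(pwr, alpha = 0.05)
  expect_lte(cal2$hit_prob, 0.05 + 1e-9)
})

test_that("planted sites are found on the correct strands and positions", {
  set.seed(603)
  motif <- iupac_to_pfm("ACGTTG", id = "m")
  bg <- simulate_background_sequence(background_model(), 300, seed = 8)
  seq_fwd <- paste0(substr(bg, 1, 100), "ACGTTG", substr(bg, 107, 300))
  hits <- scan_sequences(list(motif), c(s1 = seq_fwd), alpha = 1e-3)
  fwd <- hits[hits$strand == "+", ]
  expect_true(101 %in% fwd$start)
  # planting the reverse complement gives a minus-strand hit at the same window
  seq_rev <- paste0(substr(bg, 1, 100), revcomp("ACGTTG"), substr(bg, 107, 300))
  hits_rev <- scan_sequences(list(motif), c(s1 = seq_rev), alpha = 1e-3)
  rev <- hits_rev[hits_rev$strand == "-", ]
  expect_true(101 %in% rev$start)
  expect_equal(nrow(scan_sequences(list(motif), character(0))), 0)
})

test_that("scanning the reverse complement mirrors strands and coordinates", {
  set.seed(604)
  motif <- random_pfm(6)
  s <- simulate_background_sequence(background_model(), 400, seed = 9)
  h_fwd <- scan_sequences(list(motif), c(x = s), alpha = 0.01)
  h_rev <- scan_sequences(list(motif), c(x = revcomp(s)), alpha = 0.01)
  n <- nchar(s)
  L <- 6
  mirrored <- data.frame(start = n - h_fwd$start - L + 2L,
                         strand = ifelse(h_fwd$strand == "+", "-", "+"),
                         score = h_fwd$score)
  o1 <- mirrored[order(mirrored$start, mirrored$strand), ]
  o2 <- h_rev[order(h_rev$start, h_rev$strand), c("start", "strand", "score")]
  expect_equal(unname(as.matrix(o1[c("start")])), unname(as.matrix(o2[c("start")])))
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score, tolerance = 1e-9)
})

test_that("Markov backgrounds train, sample, and calibrate empirically", {
  set.seed(605)
  bm <- train_background_model(c("ACGTACGTGGCCAATT", "GGCCGGCCATATAT"), order = 1)
  expect_equal(rowSums(bm$trans), rep(1, 4), tolerance = 1e-12)
  s <- simulate_background_sequence(bm, 500, seed = 10)
  expect_equal(nchar(s), 500)
  p <- random_pfm(5)
  pw <- pfm_to_scoring_pwm(p)
  cal <- calibrate_cutoff(pw, bm, alpha = 0.01, sim_length = 2e4, seed = 11)
  expect_true(is.finite(cal$cutoff))
  expect_lte(cal$hit_prob, 0.011)
})
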