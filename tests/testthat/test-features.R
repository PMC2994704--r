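# The 30-feature battery and its normalization.

test_that("self-score normalization follows 2s_ij/(s_ii+s_jj) with clipping", {
  expect_equal(normalize_feature(5, 5, 5), 1)
  expect_equal(normalize_feature(0, 5, 7), 0)
  expect_equal(normalize_feature(50, 80, 120), 0.5)
  expect_equal(normalize_feature(-500, 10, 10), -1)   # clipped
  expect_true(is.na(normalize_feature(3, 0, 0)))
  expect_true(is.na(normalize_feature(3, -2, 1)))
})

test_that("identical records score 1 on every sequence-derived feature", {
  set.seed(101)
  seq <- random_aa_str(70)
  a <- toy_tf("A1", seq)
  b <- toy_tf("A2", seq)
  tree <- taxonomy_from_edges(c("K1", "S1"), c("root", "K1"))
  panel <- c(A1 = substr(seq, 11, 30), Q9 = random_aa_str(20))
  fv <- compute_feature_vector(a, b, panel = panel, taxonomy = tree)
  expect_named(fv$normalized, sprintf("f%02d", 1:30))
  expect_equal(unname(fv$normalized), rep(1, 30), tolerance = 1e-9)
})

test_that("records differing only in species differ only in the taxonomy feature", {
  set.seed(102)
  seq <- random_aa_str(70)
  tree <- taxonomy_from_edges(c("K1", "S1", "S2"), c("root", "K1", "K1"))
  a <- toy_tf("A1", seq, taxon = "S1")
  b <- toy_tf("A2", seq, taxon = "S2")
  panel <- c(A1 = substr(seq, 11, 30), Q9 = random_aa_str(20))
  fv <- compute_feature_vector(a, b, panel = panel, taxonomy = tree)
  expect_equal(unname(fv$normalized[1:29]), rep(1, 29), tolerance = 1e-9)
  expect_equal(unname(fv$normalized["f30"]), 1 / 3)
})

test_that("multi-domain features take the max over domain pairs", {
  set.seed(103)
  flank <- random_aa_str(25)
  d1 <- random_aa_str(20)
  d2 <- random_aa_str(20)
  target <- random_aa_str(20)
  two_dom <- tf_record("TD", "S1", 2, paste0(flank, d1, flank, d2, flank),
                       list(c(26, 45), c(71, 90)))
  one_dom <- tf_record("OD", "S1", 2, paste0(flank, target, flank), c(26, 45))
  fv_multi <- compute_feature_vector(two_dom, one_dom)
  v1 <- compute_feature_vector(
    tf_record("TD", "S1", 2, paste0(flank, d1, flank, d2, flank), c(26, 45)), one_dom)
  v2 <- compute_feature_vector(
    tf_record("TD", "S1", 2, paste0(flank, d1, flank, d2, flank), c(71, 90)), one_dom)
  per_pair_max <- pmax(v1$normalized[1:26], v2$normalized[1:26])
  expect_equal(fv_multi$normalized[1:26], per_pair_max, tolerance = 1e-9)
})

test_that("flank features sum the N- and C-flank alignment scores", {
  set.seed(104)
  nf <- random_aa_str(20)
  cf <- random_aa_str(20)
  dom <- random_aa_str(24)
  a <- tf_record("F1", "S1", 2, paste0(nf, dom, cf), c(21, 44))
  b <- tf_record("F2", "S1", 2, paste0(nf, dom, cf), c(21, 44))
  fv <- compute_feature_vector(a, b)
  expect_equal(unname(fv$normalized[c("f27", "f28")]), c(1, 1), tolerance = 1e-9)
  # a record whose DBD starts at position 1 has no N-flank: C-flank alone
  c1 <- tf_record("F3", "S1", 2, paste0(dom, cf), c(1, 24))
  c2 <- tf_record("F4", "S1", 2, paste0(dom, cf), c(1, 24))
  fvc <- compute_feature_vector(c1, c2)
  expect_equal(unname(fvc$normalized["f27"]), 1, tolerance = 1e-9)
})

test_that("feature vectors are symmetric in their arguments", {
  set.seed(105)
  a <- toy_tf("A1", random_aa_str(70))
  b <- toy_tf("B1", random_aa_str(70))
  tree <- taxonomy_from_edges(c("K1", "S1"), c("root", "K1"))
  fab <- compute_feature_vector(a, b, taxonomy = tree)
  fba <- compute_feature_vector(b, a, taxonomy = tree)
  expect_equal(fab$normalized, fba$normalized, tolerance = 1e-9)
})

test_that("missing taxonomy flags the phylogenetic feature", {
  set.seed(106)
  a <- toy_tf("A1", random_aa_str(70))
  b <- toy_tf("B1", random_aa_str(70))
  fv <- compute_feature_vector(a, b)
  expect_true(fv$missing["f30"])
  expect_false(any(fv$missing[sprintf("f%02d", c(1:24, 27:29))]))
})

test_that("the DBD gate uses the normalized BLOSUM62 score", {
  set.seed(107)
  seq <- random_aa_str(70)
  a <- toy_tf("A1", seq)
  b <- toy_tf("A2", seq)
  expect_equal(dbd_similarity(a, b), 1, tolerance = 1e-9)
  cfg <- feature_config()
  d <- toy_tf("D1", random_aa_str(70))
  expect_equal(dbd_similarity(a, d),
               normalized_align_score(a$dbd_seqs[1], d$dbd_seqs[1]),
               tolerance = 1e-9)
})

test_that("tf_record validates intervals and superclass", {
  expect_error(tf_record("x", "S1", 7, "ACDEF", c(1, 3)), "superclass")
  expect_error(tf_record("x", "S1", 2, "ACDEF", c(2, 9)), "invalid DBD")
  expect_error(tf_record("x", "S1", 2, "ACDEF", c(4, 2)), "invalid DBD")
  expect_warning(tf <- tf_record("x", "S1", 2, "ACDBF", c(1, 3)), "unknown residue")
  expect_equal(tf$sequence, "ACDXF")
})
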