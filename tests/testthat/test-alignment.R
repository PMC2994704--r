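# Alignment primitives: substitution matrices, NW global alignment,
# local alignment kernel, mismatch kernel, secondary structure, taxonomy.

test_that("named substitution matrices resolve and are symmetric", {
  b62 <- get_substitution_matrix("BLOSUM62")
  expect_equal(b62["W", "W"], 11)
  expect_equal(b62["A", "A"], 4)
  for (nm in c("PAM70", "CFHELIX", "KDHYDRO", "VOLUME")) {
    m <- get_substitution_matrix(nm)
    expect_true(all(abs(m - t(m)) < 1e-9))
    expect_true("X" %in% rownames(m))
  }
})

test_that("plain-text matrix files load, mirror triangles, and reject damage", {
  f <- withr::local_tempfile()
  writeLines(c("# toy identity", "A C D", "A 2 -1 -1", "C -1 2 -1", "D -1 -1 2"), f)
  m <- load_substitution_matrix(f)
  expect_equal(m["A", "A"], 2)
  expect_equal(m, t(m))
  writeLines(c("A C D", "A 2", "C -1 2", "D -1 -1 2"), f)  # lower triangle
  m2 <- load_substitution_matrix(f)
  expect_equal(m2["A", "D"], -1)
  writeLines(c("A C D", "A 2 -1 -1", "C -1 2 -1"), f)
  expect_error(load_substitution_matrix(f), "expected 3 matrix rows")
  writeLines(c("A C", "A 1 5", "C 2 1"), f)
  expect_error(load_substitution_matrix(f), "not symmetric")
})

test_that("global alignment reports score, identity and similarity fractions", {
  al <- global_align("ACDE", "ACDE", "BLOSUM62", sim_thresholds = c(0, 1, 2))
  expect_equal(al$identity, 1)
  expect_equal(unname(al$similarity), rep(1, 3))
  al2 <- global_align("ACDE", "ACDF", "BLOSUM62", gap_open = 11, gap_extend = 1,
                      sim_thresholds = c(0, 1, 2))
  expect_equal(al2$identity, 0.75)     # gapless, E/F mismatched
  expect_equal(al2$score, 16)          # 4 + 9 + 6 - 3
  expect_equal(nchar(al2$alignedA), 4)
})

test_that("NW scores and fractions match the exhaustive alignment oracle", {
  set.seed(55)
  b62 <- get_substitution_matrix("BLOSUM62")
  for (i in 1:12) {
    a <- random_aa_str(sample(2:6, 1))
    b <- random_aa_str(sample(2:6, 1))
    or <- oracle_nw(a, b, b62, 11, 1, thresholds = c(0, 1, 2))
    al <- global_align(a, b, b62, 11, 1, sim_thresholds = c(0, 1, 2))
    expect_equal(al$score, or$score, tolerance = 1e-9)
    expect_true(any(abs(or$identities - al$identity) < 1e-9))
    expect_equal(normalized_align_score(a, b),
                 max(-1, min(1, 2 * or$score /
                               (self_align_score(a, b62) + self_align_score(b, b62)))),
                 tolerance = 1e-9)
  }
})

test_that("local alignment kernel is normalized, symmetric, and tends to SW", {
  set.seed(66)
  b62 <- get_substitution_matrix("BLOSUM62")
  x <- random_aa_str(10)
  expect_equal(local_alignment_kernel(x, x), 1)
  for (i in 1:8) {
    a <- random_aa_str(8)
    b <- random_aa_str(9)
    expect_equal(local_alignment_kernel(a, b), local_alignment_kernel(b, a),
                 tolerance = 1e-12)
  }
  # at large beta, log K / beta approaches the Smith-Waterman score
  a <- "ACDEFGHIK"
  b <- "ACDWFGHIK"
  beta <- 20
  chA <- strsplit(a, "")[[1]]
  chB <- strsplit(b, "")[[1]]
  logk <- pfmtransfer:::lak_log_kernel(chA, chB, b62, beta, 11, 1)
  expect_equal(logk / beta, oracle_sw(a, b, b62, 11, 1), tolerance = 0.5)
  expect_error(local_alignment_kernel(a, b, beta = 0), "beta")
})

test_that("mismatch kernel matches the explicit feature map for (3,1)", {
  expect_equal(mismatch_kernel("ACDEACDE", "ACDEACDE", 3, 1), 1)
  expect_equal(mismatch_kernel("AAAAA", "GGGGG", 3, 0), 0)
  expect_warning(v <- mismatch_kernel("AC", "ACDEF", 3, 1), "shorter than")
  expect_equal(v, 0)
  set.seed(77)
  for (i in 1:5) {
    a <- random_aa_str(12)
    b <- random_aa_str(12)
    expect_equal(mismatch_kernel(a, b, 3, 1), oracle_mismatch_31(a, b),
                 tolerance = 1e-9)
  }
  expect_error(mismatch_kernel("ACDEF", "ACDEF", 1, 1), "k > m")
  expect_error(mismatch_kernel("ACDEF", "ACDEF", 4, 2), "m must be 0 or 1")
})

test_that("SVM-pairwise profile feature behaves at its extremes", {
  panel <- c(p1 = "ACDEFGH", p2 = "KLMNPQR", p3 = "STVWYAC")
  expect_equal(pairwise_profile_feature("ACDEFGG", "ACDEFGG", panel), 1)
  expect_warning(r <- pfmtransfer:::profile_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.na(r))
  expect_equal(pfmtransfer:::profile_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
})

test_that("secondary-structure prediction is deterministic and plausible", {
  pa <- predict_secondary_structure(strrep("A", 20))
  expect_equal(nchar(pa), 20)
  expect_gte(mean(strsplit(pa, "")[[1]] == "H"), 0.9)  # strong helix former
  pg <- predict_secondary_structure(strrep("G", 20))
  expect_false(grepl("H{6}", pg))                      # helix breaker
  set.seed(88)
  s <- random_aa_str(37)
  expect_equal(nchar(predict_secondary_structure(s)), 37)
  expect_equal(predict_secondary_structure(s), predict_secondary_structure(s))
})

test_that("taxonomy similarity follows path lengths", {
  tree <- taxonomy_from_edges(c("K1", "K2", "S1", "S2", "S3"),
                              c("root", "root", "K1", "K1", "K2"))
  expect_equal(taxonomy_similarity("S1", "S1", tree), 1)
  expect_equal(taxonomy_similarity("S1", "S2", tree), 1 / 3)  # siblings
  expect_equal(taxonomy_similarity("S1", "S3", tree),
               taxonomy_similarity("S3", "S1", tree))
  expect_warning(na <- taxonomy_similarity("S1", "SX", tree), "unknown taxon")
  expect_true(is.na(na))
  expect_error(taxonomy_from_edges(c("A", "B"), c("B", "A")), "single root|cycle")
})

test_that("newick taxonomies load via ape when available", {
  skip_if_not_installed("ape")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((S1,S2)K1,(S3,S4)K2)root;", f)
  tree <- read_taxonomy(f, "newick")
  expect_equal(taxonomy_similarity("S1", "S2", tree), 1 / 3)
})
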