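# Transfer framework: best-match selection, the outlier rule, the full
# pipeline, and the nearest-neighbour / random baselines.

# stub regressor for exercising threshold/top-k logic with controlled
# predictions
stub_model <- function(superclass = 2L, value = 0.97) {
  fit <- structure(list(value = value), class = "fixed_regressor")
  structure(list(superclass = superclass, fit = fit,
                 features = sprintf("f%02d", 1:30)),
            class = "similarity_model")
}

predict.fixed_regressor <- function(object, newdata, ...) {
  rep(object$value, nrow(as.matrix(newdata)))
}
registerS3method("predict", "fixed_regressor", predict.fixed_regressor,
                 envir = asNamespace("stats"))

test_that("the outlier ratio rule removes exactly the discordant PFM", {
  set.seed(401)
  # build P and Q with a large, known overlap distance
  P <- iupac_to_pfm("ACGTAC", id = "P")
  Q <- iupac_to_pfm("GGGGGG", id = "Q")
  dPQ <- smax(P, Q, alpha = 0.05)$d
  expect_gt(dPQ, 0.5)
  filt <- remove_outliers(list(P, P, P, Q), ratio_threshold = 1.5,
                          mosta_alpha = 0.05)
  expect_equal(filt$removed, 4L)
  expect_equal(filt$kept, 1:3)
  # ratios follow the hand computation: r_Q/r = 2, r_P/r = 2/3
  expect_equal(unname(filt$ratios[4]), 2, tolerance = 1e-9)
  expect_equal(unname(filt$ratios[1]), 2 / 3, tolerance = 1e-9)
})

test_that("symmetric pairs and identical sets pass the outlier filter", {
  set.seed(402)
  A <- random_pfm(6)
  B <- random_pfm(6)
  two <- remove_outliers(list(A, B), mosta_alpha = 0.05)
  expect_length(two$removed, 0)       # both ratios are exactly 1
  expect_equal(unname(two$ratios), c(1, 1), tolerance = 1e-9)
  same <- remove_outliers(rep(list(A), 3), mosta_alpha = 0.05)
  expect_length(same$removed, 0)      # zero mean distance guard
  single <- remove_outliers(list(A))
  expect_equal(single$kept, 1L)
})

test_that("find_best_matches applies gate, threshold and top-k", {
  fx <- shared_fixture()
  refs <- fx$corpus$refs
  q <- fx$corpus$queries[[1]]
  # stub predicting 0.97 for everyone: candidates = gate-passing refs, capped
  cand5 <- find_best_matches(q, refs, stub_model(value = 0.97),
                             taxonomy = fx$corpus$taxonomy, k = 5L,
                             cache = fx$cache)
  cand2 <- find_best_matches(q, refs, stub_model(value = 0.97),
                             taxonomy = fx$corpus$taxonomy, k = 2L,
                             cache = fx$cache)
  gate_n <- sum(vapply(refs, function(r)
    r$superclass == q$superclass &&
      dbd_similarity(q, r, cache = fx$cache) >= 0.3, logical(1)))
  expect_equal(nrow(cand5), min(5L, gate_n))
  expect_equal(nrow(cand2), min(2L, gate_n))
  expect_gte(gate_n, 4)  # in-family references pass the gate
  # stub predicting below the threshold: nothing survives
  cand0 <- find_best_matches(q, refs, stub_model(value = 0.5),
                             taxonomy = fx$corpus$taxonomy, cache = fx$cache)
  expect_equal(nrow(cand0), 0)
  expect_error(find_best_matches(q, refs, stub_model(superclass = 3L)),
               "superclass")
})

test_that("ties at the candidate boundary break by accession order", {
  fx <- shared_fixture()
  q <- fx$corpus$queries[[1]]
  cand <- find_best_matches(q, fx$corpus$refs, stub_model(value = 0.96),
                            taxonomy = fx$corpus$taxonomy, k = 3L,
                            cache = fx$cache)
  expect_equal(cand$accession, sort(cand$accession))
})

test_that("a query duplicated from a reference recovers that PFM", {
  fx <- shared_fixture()
  ref <- fx$corpus$refs[[1]]
  dup <- tf_record("ZZ_dup", ref$taxon, ref$superclass, ref$sequence,
                   ref$dbd_intervals)
  tr <- transfer_pfm(dup, fx$corpus$refs, fx$corpus$pfms, stub_model(),
                     taxonomy = fx$corpus$taxonomy, k = 1L, cache = fx$cache,
                     mosta_alpha = 0.05)
  expect_equal(tr$status, "ok")
  expect_equal(tr$candidates$accession[1], ref$accession)
  d <- smax(tr$consensus, fx$corpus$pfms[[ref$pfm_id]], alpha = 0.05)$d
  expect_lte(d, 0.05)
})

test_that("status is no_prediction when nothing passes", {
  fx <- shared_fixture()
  set.seed(403)
  # a query with an unrelated DBD never passes the 0.3 gate
  alien <- tf_record("ZZ_alien", "S1", 2, random_aa_str(90), c(31, 54))
  tr <- transfer_pfm(alien, fx$corpus$refs, fx$corpus$pfms, fx$model,
                     taxonomy = fx$corpus$taxonomy, cache = fx$cache)
  expect_equal(tr$status, "no_prediction")
  expect_null(tr$consensus)
  no_refs <- nearest_neighbor_transfer(
    tf_record("ZZ_a", "S1", 4, random_aa_str(60), c(11, 30)),
    fx$corpus$refs, fx$corpus$pfms)
  expect_equal(no_refs$status, "no_prediction")
})

test_that("nearest neighbour transfers the argmax reference verbatim", {
  fx <- shared_fixture()
  q <- fx$corpus$queries[[2]]
  nn <- nearest_neighbor_transfer(q, fx$corpus$refs, fx$corpus$pfms,
                                  cache = fx$cache)
  expect_equal(nn$status, "ok")
  scores <- vapply(fx$corpus$refs, function(r)
    dbd_similarity(q, r, cache = fx$cache), numeric(1))
  best_acc <- vapply(fx$corpus$refs, function(r) r$accession, character(1))
  best_acc <- sort(best_acc[scores == max(scores)])[1]
  expect_equal(nn$candidates$accession, best_acc)
  ref <- Filter(function(r) r$accession == best_acc, fx$corpus$refs)[[1]]
  expect_equal(nn$consensus$matrix, fx$corpus$pfms[[ref$pfm_id]]$matrix)
  # duplicating a reference makes it the nearest neighbour
  r1 <- fx$corpus$refs[[3]]
  dup <- tf_record("AA_dup", r1$taxon, r1$superclass, r1$sequence, r1$dbd_intervals)
  nn2 <- nearest_neighbor_transfer(dup, fx$corpus$refs, fx$corpus$pfms,
                                   cache = fx$cache)
  expect_equal(nn2$candidates$accession, r1$accession)
})

test_that("the random baseline is seeded, capped, and uses the usual merge", {
  fx <- shared_fixture()
  q <- fx$corpus$queries[[1]]
  r1 <- random_transfer(q, fx$corpus$refs, fx$corpus$pfms, stub_model(),
                        taxonomy = fx$corpus$taxonomy, seed = 5,
                        cache = fx$cache, mosta_alpha = 0.05)
  r2 <- random_transfer(q, fx$corpus$refs, fx$corpus$pfms, stub_model(),
                        taxonomy = fx$corpus$taxonomy, seed = 5,
                        cache = fx$cache, mosta_alpha = 0.05)
  expect_equal(r1$candidates$accession, r2$candidates$accession)
  expect_equal(r1$status, "ok")
  r3 <- random_transfer(q, fx$corpus$refs, fx$corpus$pfms, stub_model(),
                        taxonomy = fx$corpus$taxonomy, seed = 6,
                        cache = fx$cache, mosta_alpha = 0.05)
  # different seeds draw different reference sets (overwhelmingly likely)
  expect_false(identical(r1$candidates$accession, r3$candidates$accession))
})
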