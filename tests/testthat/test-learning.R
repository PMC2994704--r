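# Pair-dataset assembly and the epsilon-SVR similarity model.

make_local_tfs <- function(n, seed = 200) {
  # TFs sharing one ancestral DBD (so every pair passes the 0.3 gate) but
  # carrying distinct PFMs
  set.seed(seed)
  anc <- random_aa_str(70)
  lapply(seq_len(n), function(i) {
    ch <- strsplit(anc, "")[[1]]
    idx <- sample(70, 4)
    ch[idx] <- sample(AAS, 4, replace = TRUE)
    tf_record(sprintf("L%02d", i), "S1", 2, paste(ch, collapse = ""),
              c(11, 34), pfm_id = sprintf("P%02d", i))
  })
}

test_that("dataset assembly applies the local-pair gate and label-1 guard", {
  tfs <- make_local_tfs(4)
  set.seed(201)
  pfms <- setNames(lapply(1:4, function(i) random_pfm(6, sprintf("P%02d", i))),
                   sprintf("P%02d", 1:4))
  ds <- assemble_pair_dataset(tfs, pfms, 2, mosta_alpha = 0.05)
  expect_s3_class(ds, "pair_dataset")
  expect_equal(nrow(ds$pairs), 6)   # all 4 TFs mutually local and distinct
  expect_true(all(ds$labels < 1 - 1e-9))

  # two TFs assigned the same PFM: that pair disappears
  pfms_dup <- pfms
  pfms_dup[["P02"]] <- pfms_dup[["P01"]]
  ds_dup <- assemble_pair_dataset(tfs, pfms_dup, 2, mosta_alpha = 0.05)
  expect_equal(nrow(ds_dup$pairs), 5)
  expect_false(any(ds_dup$pairs$acc_i == "L01" & ds_dup$pairs$acc_j == "L02"))

  # a DBD-dissimilar TF contributes no pairs
  set.seed(202)
  far <- tf_record("L99", "S1", 2, random_aa_str(70), c(11, 34), pfm_id = "P99")
  pfms[["P99"]] <- random_pfm(6, "P99")
  ds_far <- assemble_pair_dataset(c(tfs, list(far)), pfms, 2, mosta_alpha = 0.05)
  expect_false("L99" %in% c(ds_far$pairs$acc_i, ds_far$pairs$acc_j))
})

test_that("assembly errors are informative", {
  tfs <- make_local_tfs(2)
  pfms <- setNames(lapply(1:2, function(i) random_pfm(6, sprintf("P%02d", i))),
                   sprintf("P%02d", 1:2))
  expect_error(assemble_pair_dataset(tfs, pfms, 3), "at least 2 TFs")
  expect_error(assemble_pair_dataset(tfs, pfms["P01"], 2), "not provided")
})

test_that("a noiseless linear relationship is recovered within epsilon", {
  set.seed(210)
  n <- 60
  # signal confined to one feature so the RBF regression can interpolate
  X <- matrix(0, n, 30, dimnames = list(NULL, sprintf("f%02d", 1:30)))
  X[, 1] <- runif(n, -1, 1)
  y <- 0.5 + 0.4 * X[, 1]
  ds <- structure(list(superclass = 2L, X = X, labels = y,
                       pairs = data.frame(acc_i = as.character(1:n),
                                          acc_j = as.character(1:n), label = y)),
                  class = "pair_dataset")
  grid <- data.frame(cost = 32, epsilon = 0.01, gamma = 0.125)
  m <- train_superclass_model(ds, grid, runs = 2, folds = 5, seed = 1)
  expect_lte(m$cv_aae, 0.01 + 0.01)
})

test_that("permuted labels perform like the mean predictor", {
  set.seed(211)
  n <- 60
  X <- matrix(runif(n * 30, -1, 1), n, 30, dimnames = list(NULL, sprintf("f%02d", 1:30)))
  y <- sample(0.5 + 0.4 * runif(n))
  ds <- structure(list(superclass = 2L, X = X, labels = y,
                       pairs = data.frame(acc_i = as.character(1:n),
                                          acc_j = as.character(1:n), label = y)),
                  class = "pair_dataset")
  grid <- data.frame(cost = 2, epsilon = 0.05, gamma = 0.125)
  m <- train_superclass_model(ds, grid, runs = 3, folds = 5, seed = 2)
  mean_aae <- mean(abs(y - mean(y)))
  expect_lt(abs(m$cv_aae - mean_aae) / mean_aae, 0.35)
})

test_that("training is deterministic given the seed", {
  fx <- shared_fixture()
  grid <- expand.grid(cost = c(0.5, 8), epsilon = 0.05, gamma = c(0.125, 0.5))
  m1 <- train_superclass_model(fx$dataset, grid, runs = 2, folds = 4, seed = 7)
  m2 <- train_superclass_model(fx$dataset, grid, runs = 2, folds = 4, seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_equal(m1$cv_report$aae, m2$cv_report$aae)
  expect_equal(nrow(m1$cv_report), nrow(grid) * 2 * 4)
})

test_that("degenerate labels are rejected", {
  X <- matrix(0.5, 10, 30, dimnames = list(NULL, sprintf("f%02d", 1:30)))
  ds <- structure(list(superclass = 2L, X = X, labels = rep(0.7, 10),
                       pairs = data.frame()), class = "pair_dataset")
  expect_error(train_superclass_model(ds, data.frame(cost = 1, epsilon = 0.1,
                                                     gamma = 0.1)),
               "constant")
})

test_that("predictions are clipped to [0,1] and track training labels", {
  fx <- shared_fixture()
  m <- fx$model
  set.seed(212)
  for (i in 1:100) {
    v <- setNames(runif(30, -1, 1), sprintf("f%02d", 1:30))
    p <- predict_similarity(m, v)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  # near-interpolating refit on the training rows stays close to labels
  grid <- data.frame(cost = 32, epsilon = 0.01, gamma = 0.5)
  mi <- train_superclass_model(fx$dataset, grid, runs = 1, folds = 5, seed = 3)
  X <- fx$dataset$X
  X[is.na(X)] <- 0
  preds <- predict_similarity(mi, X)
  expect_lt(mean(abs(preds - fx$dataset$labels)), 0.05)
  expect_error(predict_similarity(list(), v), "not a trained")
})

test_that("models persist and reload to identical predictions", {
  fx <- shared_fixture()
  dir <- withr::local_tempdir()
  save_similarity_model(fx$model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_similarity_model(dir, fx$dataset)
  X <- fx$dataset$X
  X[is.na(X)] <- 0
  expect_equal(predict_similarity(m2, X), predict_similarity(fx$model, X),
               tolerance = 1e-9)
})
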