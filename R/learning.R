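# Learning the PFM-similarity metric.
#
# For every eligible TF pair of one structural superclass, the 30 normalized
# sequence features form the predictors and the normalized overlap
# similarity of their PFMs the label. Eligible ("local") pairs have a
# normalized BLOSUM62 DBD score above the gate (default 0.3); pairs whose
# PFM similarity equals 1 are excluded so that TFs annotated with the same
# PFM are never learned. An epsilon-SVR with RBF kernel is tuned by grid
# search under a 10-run 5-fold cross-validation; the average absolute error
# (AAE) on the held-out folds is the model selection criterion.

#' Default hyperparameter grid for the epsilon-SVR
#'
#' @return data.frame with columns `cost`, `epsilon`, `gamma`.
#' @export
default_svr_grid <- function() {
  expand.grid(cost = c(0.125, 0.5, 2, 8, 32),
              epsilon = c(0.01, 0.05, 0.1),
              gamma = c(0.03125, 0.125, 0.5, 2))
}

#' Assemble the labeled pair dataset of one superclass
#'
#' @param tfs list of `tf_record`s with `pfm_id` set.
#' @param pfms named list of `pfm` objects (names = pfm ids).
#' @param superclass structural superclass (1-5) to restrict to.
#' @param config a [feature_config()].
#' @param taxonomy optional `taxonomy_tree` for feature f30.
#' @param seed seed for the optional subsample.
#' @param max_pairs optional cap on the number of pairs (seeded subsample).
#' @param mosta_alpha type-I rate for the PFM hit models labelling the pairs.
#' @param panel SVM-pairwise panel (default: the superclass' TFs in `tfs`);
#'   pass the reference panel explicitly when assembling held-out test
#'   pairs so train and test features share one panel.
#' @param cache optional [new_feature_cache()].
#' @return object of class `pair_dataset`: `pairs` (accessions + label),
#'   feature matrix `X` (n x 30), `labels`, `superclass`.
#' @export
assemble_pair_dataset <- function(tfs, pfms, superclass, config = feature_config(),
                                  taxonomy = NULL, seed = 1L, max_pairs = NULL,
                                  mosta_alpha = 1e-3, panel = NULL, cache = NULL) {
  tfs <- Filter(function(tf) tf$superclass == superclass && !is.null(tf$pfm_id), tfs)
  if (length(tfs) < 2L) stopf("need at least 2 TFs with PFM in superclass %d", superclass)
  missing_pfm <- setdiff(vapply(tfs, function(tf) tf$pfm_id, character(1)), names(pfms))
  if (length(missing_pfm)) stopf("PFM(s) not provided: %s", paste(missing_pfm, collapse = ", "))
  if (is.null(cache)) cache <- new_feature_cache()
  if (is.null(panel)) panel <- reference_panel(tfs, superclass)
  hm_of <- function(id) hit_model_memo(pfms[[id]], alpha = mosta_alpha)
  rows <- list()
  n <- length(tfs)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    gate <- dbd_similarity(tfs[[i]], tfs[[j]], config, cache)
    if (is.na(gate) || gate < config$dbd_gate) next
    label <- smax_memo(hm_of(tfs[[i]]$pfm_id), hm_of(tfs[[j]]$pfm_id))$s_norm
    if (label >= 1 - 1e-9) next  # duplicate-PFM guard
    fv <- compute_feature_vector(tfs[[i]], tfs[[j]], config, panel, taxonomy, cache)
    rows[[length(rows) + 1L]] <- list(acc_i = tfs[[i]]$accession,
                                      acc_j = tfs[[j]]$accession,
                                      label = label, fv = fv$normalized)
  }
  if (length(rows) == 0L)
    stopf("no eligible pairs in superclass %d; consider lowering the DBD gate (%.2f)",
          superclass, config$dbd_gate)
  if (!is.null(max_pairs) && length(rows) > max_pairs) {
    set.seed(derive_seed(seed, "pair_subsample"))
    rows <- rows[sort(sample.int(length(rows), max_pairs))]
  }
  X <- do.call(rbind, lapply(rows, function(r) r$fv))
  rownames(X) <- NULL
  structure(list(superclass = as.integer(superclass),
                 pairs = data.frame(
                   acc_i = vapply(rows, function(r) r$acc_i, character(1)),
                   acc_j = vapply(rows, function(r) r$acc_j, character(1)),
                   label = vapply(rows, function(r) r$label, numeric(1)),
                   stringsAsFactors = FALSE),
                 X = X,
                 labels = vapply(rows, function(r) r$label, numeric(1))),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("pair dataset: superclass %d, %d pairs, labels in [%.3f, %.3f]\n",
              x$superclass, length(x$labels), min(x$labels), max(x$labels)))
  invisible(x)
}

impute_features <- function(X, features = FEATURE_IDS) {
  X <- X[, features, drop = FALSE]
  n_missing <- sum(is.na(X))
  if (n_missing > 0) {
    message(sprintf("imputing %d missing feature value(s) to 0", n_missing))
    X[is.na(X)] <- 0
  }
  X
}

cv_partition <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

svr_fit <- function(X, y, cost, epsilon, gamma) {
  # when the epsilon tube swallows every row libsvm keeps no support
  # vectors and cannot predict ("Model is empty"); such a fit is the
  # constant mean predictor
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$tot.nSV == 0L)
    structure(list(mu = mean(y)), class = "constant_regressor")
  else fit
}

#' @export
predict.constant_regressor <- function(object, newdata, ...) {
  rep(object$mu, nrow(as.matrix(newdata)))
}

#' Train the per-superclass SVR similarity model
#'
#' For every grid point the mean AAE over `runs` repeated random
#' `folds`-fold partitions is computed; the hyperparameters with minimal
#' mean CV-AAE are refit on all rows. Deterministic given `seed`.
#'
#' @param dataset a `pair_dataset`.
#' @param grid hyperparameter data.frame (`cost`, `epsilon`, `gamma`).
#' @param runs,folds cross-validation design (default 10 x 5).
#' @param seed integer seed for the fold partitions.
#' @param features feature subset to train on (default all 30).
#' @return object of class `similarity_model` with `hyperparameters`,
#'   fitted `fit`, `cv_report` (per grid point/run/fold AAE), `cv_aae`.
#' @export
train_superclass_model <- function(dataset, grid = default_svr_grid(),
                                   runs = 10L, folds = 5L, seed = 1L,
                                   features = FEATURE_IDS) {
  stopifnot(inherits(dataset, "pair_dataset"))
  y <- dataset$labels
  if (length(y) < folds) stopf("need at least %d rows for %d-fold CV", folds, folds)
  if (sd(y) == 0) stopf("degenerate (constant) labels; nothing to learn")
  X <- impute_features(dataset$X, features)
  parts <- lapply(seq_len(runs), function(r)
    cv_partition(length(y), folds, derive_seed(seed, paste0("cv_run", r))))
  report <- list()
  means <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aaes <- matrix(NA_real_, runs, folds)
    for (r in seq_len(runs)) for (f in seq_len(folds)) {
      test <- parts[[r]] == f
      if (all(test) || !any(test)) next
      fit <- svr_fit(X[!test, , drop = FALSE], y[!test],
                     grid$cost[g], grid$epsilon[g], grid$gamma[g])
      pred <- clip01(predict(fit, X[test, , drop = FALSE]))
      aaes[r, f] <- mean(abs(pred - y[test]))
    }
    means[g] <- mean(aaes, na.rm = TRUE)
    report[[g]] <- data.frame(cost = grid$cost[g], epsilon = grid$epsilon[g],
                              gamma = grid$gamma[g],
                              run = rep(seq_len(runs), each = folds),
                              fold = rep(seq_len(folds), runs),
                              aae = as.vector(t(aaes)))
  }
  best <- which.min(means)
  fit <- svr_fit(X, y, grid$cost[best], grid$epsilon[best], grid$gamma[best])
  structure(list(superclass = dataset$superclass,
                 hyperparameters = as.list(grid[best, , drop = FALSE]),
                 fit = fit,
                 features = features,
                 cv_aae = means[best],
                 cv_grid_aae = cbind(grid, mean_cv_aae = means),
                 cv_report = do.call(rbind, report),
                 runs = runs, folds = folds, seed = seed),
            class = "similarity_model")
}

#' @export
print.similarity_model <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf("SVR similarity model (superclass %d): C=%g, epsilon=%g, gamma=%g; CV AAE=%.4f (%dx%d CV, %d features)\n",
              x$superclass, h$cost, h$epsilon, h$gamma, x$cv_aae,
              x$runs, x$folds, length(x$features)))
  invisible(x)
}

#' Predict PFM similarity from a feature vector
#'
#' Missing features are imputed to 0 (the post-normalization neutral value)
#' and the regression output is clipped to `[0, 1]`.
#'
#' @param model a `similarity_model`.
#' @param fv a `feature_vector`, a named numeric vector, or a matrix with
#'   feature columns.
#' @return predicted similarity (vector), each value in `[0, 1]`.
#' @export
predict_similarity <- function(model, fv) {
  if (!inherits(model, "similarity_model") || is.null(model$fit))
    stopf("model is not a trained similarity_model")
  X <- if (inherits(fv, "feature_vector")) matrix(fv$normalized, nrow = 1,
                                                  dimnames = list(NULL, FEATURE_IDS))
       else if (is.matrix(fv)) fv
       else matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))
  X <- suppressMessages(impute_features(X, model$features))
  unname(clip01(predict(model$fit, X)))
}

#' Persist / restore a similarity model
#'
#' The model directory holds the hyperparameters and CV report as
#' JSON/TSV plus the libsvm state written by [e1071::write.svm] style
#' serialization via `saveRDS`-free plain text (feature weights are not
#' portable as text, so the fitted support vectors and coefficients are
#' stored numerically).
#'
#' @param model a `similarity_model`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_similarity_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(superclass = model$superclass,
               hyperparameters = model$hyperparameters,
               features = model$features,
               cv_aae = model$cv_aae,
               runs = model$runs, folds = model$folds, seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write.table(model$cv_report, file.path(dir, "cv_report.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(model$fit$SV)) {
    write.table(cbind(coef = as.vector(model$fit$coefs), model$fit$SV),
                file.path(dir, "support_vectors.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(format(c(model$fit$rho), digits = 17), file.path(dir, "rho.txt"))
  }
  invisible(dir)
}

#' @rdname save_similarity_model
#' @param dataset the `pair_dataset` used for training (the libsvm state is
#'   reconstructed by refitting with the saved hyperparameters).
#' @export
load_similarity_model <- function(dir, dataset) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  X <- impute_features(dataset$X, meta$features)
  fit <- svr_fit(X, dataset$labels, meta$hyperparameters$cost,
                 meta$hyperparameters$epsilon, meta$hyperparameters$gamma)
  structure(list(superclass = meta$superclass,
                 hyperparameters = as.list(meta$hyperparameters),
                 fit = fit, features = meta$features, cv_aae = meta$cv_aae,
                 cv_report = read.delim(file.path(dir, "cv_report.tsv")),
                 runs = meta$runs, folds = meta$folds, seed = meta$seed),
            class = "similarity_model")
}
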