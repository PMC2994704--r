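# Validation harness: regression quality of the learned similarity metric
# (Pearson r, AAE), transfer-error comparison of the SVR framework against
# the nearest-neighbour and random baselines, and the single-feature
# regression analysis.

#' Average absolute error between predicted and annotated PFMs
#'
#' Mean, over queries, of the normalized overlap distance (d = 1 - s_norm,
#' on [0,1]) between each predicted and true PFM.
#'
#' @param predicted_pfms,true_pfms equal-length lists of `pfm` objects.
#' @param mosta_alpha type-I rate of the hit models.
#' @return the AAE, a number in `[0, 1]`.
#' @export
average_absolute_error <- function(predicted_pfms, true_pfms, mosta_alpha = 1e-3) {
  if (length(predicted_pfms) != length(true_pfms) || length(true_pfms) == 0L)
    stopf("need equally many (>= 1) predicted and true PFMs")
  mean(mapply(function(p, t)
    smax_memo(hit_model_memo(p, mosta_alpha), hit_model_memo(t, mosta_alpha))$d,
    predicted_pfms, true_pfms))
}

#' Evaluate a similarity model on held-out pairs
#'
#' @param model a `similarity_model`.
#' @param test_pairs a `pair_dataset` not used in training.
#' @return object of class `evaluation_report`: `pearson_r` (NA when the
#'   predictions are constant), `aae`, `n`, per-pair residuals.
#' @export
evaluate_similarity_model <- function(model, test_pairs) {
  stopifnot(inherits(test_pairs, "pair_dataset"))
  X <- suppressMessages(impute_features(test_pairs$X, model$features))
  pred <- clip01(predict(model$fit, X))
  y <- test_pairs$labels
  r <- if (sd(pred) == 0 || sd(y) == 0) {
    warnf("constant predictions or labels; Pearson r reported as missing")
    NA_real_
  } else cor(pred, y)
  structure(list(superclass = test_pairs$superclass,
                 pearson_r = r, aae = mean(abs(pred - y)),
                 n = length(y), predicted = pred, observed = y),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation (superclass %d, n=%d): Pearson r=%s, AAE=%.4f\n",
              x$superclass, x$n,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r),
              x$aae))
  invisible(x)
}

#' Compare the SVR transfer framework against the baselines
#'
#' Runs the SVR transfer, the nearest-neighbour transfer and `random_reps`
#' seeded repetitions of the random transfer for every query TF, and
#' restricts all methods to the queries where both the SVR framework and
#' the nearest neighbour produced an output, so every method is evaluated
#' on the same query set. Queries are processed in accession order, so the
#' result is invariant to the input order.
#'
#' @param queries list of test `tf_record`s with known PFMs (`pfm_id` set).
#' @param refs list of reference `tf_record`s.
#' @param pfms named list of all PFMs (references and query truths).
#' @param models named list of `similarity_model`s, keyed by superclass
#'   (`"1"`..`"5"`).
#' @param config a [feature_config()].
#' @param taxonomy optional `taxonomy_tree`.
#' @param threshold,k,outlier_ratio transfer parameters.
#' @param seed integer seed for the random baseline.
#' @param random_reps repetitions of the random baseline (default 10).
#' @param mosta_alpha type-I rate of the hit models behind all PFM
#'   distances (outlier filter and error measurement).
#' @return object of class `framework_comparison`: per-query distances
#'   (`per_query`), per-method/superclass summary (`summary`), transfer
#'   rate, and the sign-test p-value of SVR vs random.
#' @export
compare_frameworks <- function(queries, refs, pfms, models,
                               config = feature_config(), taxonomy = NULL,
                               threshold = 0.95, k = 5L, outlier_ratio = 1.5,
                               seed = 1L, random_reps = 10L, mosta_alpha = 1e-3) {
  cache <- new_feature_cache()
  queries <- queries[order(vapply(queries, function(q) q$accession, character(1)))]
  rows <- list()
  n_ok <- 0L
  for (q in queries) {
    model <- models[[as.character(q$superclass)]]
    if (is.null(model) || is.null(q$pfm_id)) next
    truth <- pfms[[q$pfm_id]]
    svr <- transfer_pfm(q, refs, pfms, model, config, taxonomy,
                        threshold, k, outlier_ratio, cache, mosta_alpha)
    if (svr$status == "ok") n_ok <- n_ok + 1L
    nn <- nearest_neighbor_transfer(q, refs, pfms, config, cache)
    if (svr$status != "ok" || nn$status != "ok") next
    d_rand <- vapply(seq_len(random_reps), function(rep) {
      rt <- random_transfer(q, refs, pfms, model, config, taxonomy, threshold,
                            k, outlier_ratio,
                            seed = derive_seed(seed, paste0("rep", rep)),
                            cache = cache, mosta_alpha = mosta_alpha)
      if (rt$status == "ok")
        smax_memo(hit_model_memo(rt$consensus, mosta_alpha),
                  hit_model_memo(truth, mosta_alpha))$d
      else NA_real_
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      query = q$accession, superclass = q$superclass,
      d_svr = smax_memo(hit_model_memo(svr$consensus, mosta_alpha),
                        hit_model_memo(truth, mosta_alpha))$d,
      d_nn = smax_memo(hit_model_memo(nn$consensus, mosta_alpha),
                       hit_model_memo(truth, mosta_alpha))$d,
      d_random = mean(d_rand, na.rm = TRUE))
  }
  per_query <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), superclass = integer(0),
               d_svr = numeric(0), d_nn = numeric(0), d_random = numeric(0))
  summarize <- function(v) c(n = length(v), aae = mean(v),
                             median = median(v),
                             q25 = unname(quantile(v, 0.25)),
                             q75 = unname(quantile(v, 0.75)))
  summ <- do.call(rbind, lapply(split(per_query, per_query$superclass), function(df) {
    do.call(rbind, lapply(c("d_svr", "d_nn", "d_random"), function(mname)
      data.frame(superclass = df$superclass[1],
                 method = sub("^d_", "", mname), t(summarize(df[[mname]])))))
  }))
  rownames(summ) <- NULL
  # paired sign test SVR vs random over queries with differing distances
  diff <- per_query$d_svr - per_query$d_random
  nz <- diff[abs(diff) > 1e-12]
  p_sign <- if (length(nz) == 0L) NA_real_ else
    stats::binom.test(sum(nz < 0), length(nz), alternative = "greater")$p.value
  structure(list(per_query = per_query, summary = summ,
                 transfer_rate = n_ok / max(1L, length(queries)),
                 sign_test_p_svr_vs_random = p_sign,
                 seed = seed, random_reps = random_reps),
            class = "framework_comparison")
}

#' @export
print.framework_comparison <- function(x, ...) {
  cat(sprintf("framework comparison on %d query TF(s) (transfer rate %.1f%%)\n",
              nrow(x$per_query), 100 * x$transfer_rate))
  if (nrow(x$per_query)) {
    cat(sprintf("  AAE: SVR %.4f, NN %.4f, random %.4f; sign test SVR<random p=%.3g\n",
                mean(x$per_query$d_svr), mean(x$per_query$d_nn),
                mean(x$per_query$d_random), x$sign_test_p_svr_vs_random))
  }
  invisible(x)
}

#' Single-feature regression analysis
#'
#' Trains one SVR per individual feature plus one on all 30 features under
#' the same cross-validation design, and reports each model's mean CV-AAE;
#' used to quantify the benefit of combining the feature battery.
#'
#' @param dataset a `pair_dataset`.
#' @param grid hyperparameter grid (see [default_svr_grid()]).
#' @param runs,folds cross-validation design.
#' @param seed integer seed.
#' @param features features to analyze individually (default all 30).
#' @return data.frame with one row per feature plus an `"all"` row,
#'   columns `feature`, `cv_aae`.
#' @export
single_feature_analysis <- function(dataset, grid = default_svr_grid(),
                                    runs = 10L, folds = 5L, seed = 1L,
                                    features = FEATURE_IDS) {
  fit_aae <- function(subset) {
    m <- train_superclass_model(dataset, grid, runs, folds, seed, features = subset)
    m$cv_aae
  }
  per <- vapply(features, function(f) fit_aae(f), numeric(1))
  rbind(data.frame(feature = features, cv_aae = unname(per)),
        data.frame(feature = "all", cv_aae = fit_aae(features)))
}
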