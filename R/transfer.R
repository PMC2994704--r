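# The PFM transfer framework.
#
# A query TF (sequence, DBD annotation, superclass, species) is compared to
# every reference TF of the same superclass whose DBD similarity passes the
# 0.3 gate; the SVR model predicts the PFM similarity of each such pair.
# References above the best-match threshold (default 0.95) are kept, capped
# at the top k (default 5); their PFMs pass an outlier filter and are merged
# into the predicted consensus PFM. Nearest-neighbour and random-resampling
# baselines share the same machinery.

transfer_result <- function(query, candidates, outliers_removed, consensus, status) {
  structure(list(query = query, candidates = candidates,
                 outliers_removed = outliers_removed,
                 consensus = consensus, status = status),
            class = "transfer_result")
}

no_prediction <- function(query) {
  transfer_result(query, data.frame(accession = character(0), pred = numeric(0)),
                  character(0), NULL, "no_prediction")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer for %s: %s", x$query, x$status))
  if (x$status == "ok")
    cat(sprintf(" (%d candidate(s), %d outlier(s) removed, consensus length %d)",
                nrow(x$candidates), length(x$outliers_removed),
                pfm_length(x$consensus)))
  cat("\n")
  invisible(x)
}

#' Find best-matching reference TFs for a query
#'
#' References of the query's superclass passing the DBD gate are scored by
#' the SVR model; those with predicted similarity at least `threshold` are
#' ranked (ties by accession) and the top `k` returned.
#'
#' @param query a `tf_record`.
#' @param refs list of reference `tf_record`s with PFMs.
#' @param model the `similarity_model` of the query's superclass.
#' @param config a [feature_config()].
#' @param taxonomy optional `taxonomy_tree`.
#' @param threshold best-match similarity threshold (default 0.95).
#' @param k maximum number of candidates kept (default 5).
#' @param cache optional [new_feature_cache()].
#' @return data.frame with columns `accession`, `pred` (may be empty).
#' @export
find_best_matches <- function(query, refs, model, config = feature_config(),
                              taxonomy = NULL, threshold = 0.95, k = 5L,
                              cache = NULL) {
  if (model$superclass != query$superclass)
    stopf("model superclass %d does not match query superclass %d",
          model$superclass, query$superclass)
  refs <- same_superclass_refs(query, refs)
  if (length(refs) == 0L)
    return(data.frame(accession = character(0), pred = numeric(0)))
  panel <- reference_panel(refs, query$superclass)
  rows <- list()
  for (ref in refs) {
    gate <- dbd_similarity(query, ref, config, cache)
    if (is.na(gate) || gate < config$dbd_gate) next
    fv <- compute_feature_vector(query, ref, config, panel, taxonomy, cache)
    rows[[length(rows) + 1L]] <-
      data.frame(accession = ref$accession,
                 pred = predict_similarity(model, fv))
  }
  if (length(rows) == 0L)
    return(data.frame(accession = character(0), pred = numeric(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[cand$pred >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$pred, cand$accession), , drop = FALSE]
  head(cand, k)
}

same_superclass_refs <- function(query, refs) {
  refs <- Filter(function(tf) tf$superclass == query$superclass &&
                   tf$accession != query$accession, refs)
  refs[order(vapply(refs, function(tf) tf$accession, character(1)))]
}

#' Remove outlier PFMs before merging
#'
#' For each candidate PFM t the mean overlap distance `r_t` to all other
#' candidates and the overall mean pairwise distance `r` are computed in a
#' single pass; t is removed iff `r_t / r` exceeds `ratio_threshold`.
#' Singletons pass through; when all pairwise distances are 0 nothing is
#' removed.
#'
#' @param pfms list of candidate `pfm` objects.
#' @param ratio_threshold removal threshold on `r_t / r` (default 1.5).
#' @param mosta_alpha type-I rate for the hit models behind the distances.
#' @return list with `kept` and `removed` (integer indices) and `ratios`.
#' @export
remove_outliers <- function(pfms, ratio_threshold = 1.5, mosta_alpha = 1e-3) {
  n <- length(pfms)
  if (n < 2L) return(list(kept = seq_len(n), removed = integer(0),
                          ratios = rep(NA_real_, n)))
  hms <- lapply(pfms, hit_model_memo, alpha = mosta_alpha)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- smax_memo(hms[[i]], hms[[j]])$d
  r_t <- rowSums(D) / (n - 1L)
  r_bar <- mean(D[upper.tri(D)])
  if (r_bar <= 0) return(list(kept = seq_len(n), removed = integer(0),
                              ratios = rep(NA_real_, n)))
  ratios <- r_t / r_bar
  removed <- which(ratios > ratio_threshold)
  list(kept = setdiff(seq_len(n), removed), removed = removed, ratios = ratios)
}

candidate_pfms <- function(candidates, refs, pfms) {
  acc2pfm <- setNames(lapply(refs, function(tf) pfms[[tf$pfm_id]]),
                      vapply(refs, function(tf) tf$accession, character(1)))
  lapply(candidates$accession, function(a) acc2pfm[[a]])
}

#' Transfer a PFM to a query TF
#'
#' Full prediction pipeline: best matches via the SVR metric, outlier
#' filter, progressive merge of the surviving reference PFMs into the
#' predicted consensus. Returns status `"no_prediction"` when no reference
#' passes the gate and threshold.
#'
#' @inheritParams find_best_matches
#' @param pfms named list of reference PFMs (names = pfm ids).
#' @param outlier_ratio outlier removal threshold (default 1.5).
#' @param mosta_alpha type-I rate of the hit models behind the outlier
#'   distances.
#' @return a `transfer_result`.
#' @export
transfer_pfm <- function(query, refs, pfms, model, config = feature_config(),
                         taxonomy = NULL, threshold = 0.95, k = 5L,
                         outlier_ratio = 1.5, cache = NULL, mosta_alpha = 1e-3) {
  if (length(query$dbd_intervals) == 0L) stopf("query TF lacks a DBD annotation")
  cand <- find_best_matches(query, refs, model, config, taxonomy, threshold, k, cache)
  finish_transfer(query$accession, cand, refs, pfms, outlier_ratio, mosta_alpha)
}

finish_transfer <- function(query_acc, cand, refs, pfms, outlier_ratio,
                            mosta_alpha = 1e-3) {
  if (nrow(cand) == 0L) return(no_prediction(query_acc))
  cps <- candidate_pfms(cand, refs, pfms)
  filt <- remove_outliers(cps, ratio_threshold = outlier_ratio,
                          mosta_alpha = mosta_alpha)
  kept <- cps[filt$kept]
  consensus <- merge_pfms(kept, id = paste0(query_acc, "_pred"))
  transfer_result(query_acc, cand, cand$accession[filt$removed], consensus, "ok")
}

#' Nearest-neighbour PFM transfer baseline
#'
#' Transfers, verbatim, the PFM of the reference with the highest
#' normalized BLOSUM62 DBD alignment score (ties broken by accession).
#'
#' @inheritParams transfer_pfm
#' @return a `transfer_result`.
#' @export
nearest_neighbor_transfer <- function(query, refs, pfms,
                                      config = feature_config(), cache = NULL) {
  refs <- same_superclass_refs(query, refs)
  if (length(refs) == 0L) return(no_prediction(query$accession))
  scores <- vapply(refs, function(ref)
    dbd_similarity(query, ref, config, cache), numeric(1))
  best <- which(scores == max(scores))[1L]  # refs pre-sorted by accession
  cand <- data.frame(accession = refs[[best]]$accession, pred = scores[best])
  transfer_result(query$accession, cand, character(0),
                  pfms[[refs[[best]]$pfm_id]], "ok")
}

#' Random PFM transfer baseline
#'
#' Runs [find_best_matches()] to fix the number m of best matches, then
#' replaces them by m references drawn uniformly without replacement from
#' all same-superclass references, and proceeds with the usual outlier
#' filter and merge. Deterministic given `seed`.
#'
#' @inheritParams transfer_pfm
#' @param seed integer seed for the draws.
#' @return a `transfer_result`.
#' @export
random_transfer <- function(query, refs, pfms, model, config = feature_config(),
                            taxonomy = NULL, threshold = 0.95, k = 5L,
                            outlier_ratio = 1.5, seed = 1L, cache = NULL,
                            mosta_alpha = 1e-3) {
  cand <- find_best_matches(query, refs, model, config, taxonomy, threshold, k, cache)
  m <- nrow(cand)
  if (m == 0L) return(no_prediction(query$accession))
  pool <- same_superclass_refs(query, refs)
  if (m > length(pool)) {
    warnf("requested %d random references but only %d available", m, length(pool))
    m <- length(pool)
  }
  set.seed(derive_seed(seed, paste0("rand|", query$accession)))
  draw <- sort(sample.int(length(pool), m))
  cand <- data.frame(accession = vapply(pool[draw], function(tf) tf$accession,
                                        character(1)),
                     pred = rep(NA_real_, m))
  finish_transfer(query$accession, cand, refs, pfms, outlier_ratio, mosta_alpha)
}
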