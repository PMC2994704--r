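# Pipeline orchestration: file-based stages over the package's functions,
# with a resolved-config log so every artifact can be traced to the exact
# settings and seeds that produced it.

#' Pipeline run configuration
#'
#' Defaults mirror the framework's documented settings: DBD gate 0.3,
#' best-match threshold 0.95, top-k 5, outlier ratio 1.5, hit-model alpha
#' 1e-3, 10x5 cross-validation over the default SVR grid.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @param ... overrides of the defaults (see source for names).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              dbd_gate = 0.3, best_match = 0.95, top_k = 5L,
              outlier_ratio = 1.5, mosta_alpha = 1e-3,
              svr_grid = default_svr_grid(), runs = 10L, folds = 5L,
              random_reps = 10L,
              simulate = list(n_families = 24L, members_per_family = 6L,
                              coupling = 0.9, superclasses = 1:5),
              feature_overrides = list())
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown run_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$dbd_gate >= -1, cfg$dbd_gate <= 1,
            cfg$best_match >= 0, cfg$best_match <= 1,
            cfg$top_k >= 1, cfg$outlier_ratio > 0,
            cfg$mosta_alpha > 0, cfg$mosta_alpha < 1)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg)[setdiff(names(cfg), "out_dir")], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

log_event <- function(cfg, stage, message) {
  rec <- list(stage = stage, message = message, seed = cfg$seed,
              config_hash = config_hash(cfg),
              version = as.character(utils::packageVersion("pfmtransfer")))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(cfg$out_dir, "run.log.jsonl"), append = TRUE, sep = "")
}

feature_config_of <- function(cfg) {
  do.call(feature_config, c(list(dbd_gate = cfg$dbd_gate), cfg$feature_overrides))
}

#' Write / read a TF table
#'
#' Tab-separated columns: `accession`, `taxon`, `superclass`, `sequence`,
#' `dbd` (semicolon-joined `start-end` intervals), `pfm_id` (empty when
#' unknown).
#'
#' @param tfs list of `tf_record`s.
#' @param path file path.
#' @return `path` (write) or list of `tf_record`s (read).
#' @export
write_tf_table <- function(tfs, path) {
  df <- data.frame(
    accession = vapply(tfs, function(x) x$accession, character(1)),
    taxon = vapply(tfs, function(x) x$taxon, character(1)),
    superclass = vapply(tfs, function(x) x$superclass, integer(1)),
    sequence = vapply(tfs, function(x) x$sequence, character(1)),
    dbd = vapply(tfs, function(x)
      paste(vapply(x$dbd_intervals, function(iv)
        paste(iv, collapse = "-"), character(1)), collapse = ";"), character(1)),
    pfm_id = vapply(tfs, function(x) x$pfm_id %||% "", character(1)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tf_table
#' @export
read_tf_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    ivs <- lapply(strsplit(df$dbd[i], ";")[[1]], function(s)
      as.integer(strsplit(s, "-")[[1]]))
    tf_record(df$accession[i], df$taxon[i], as.integer(df$superclass[i]),
              df$sequence[i], ivs,
              pfm_id = if (nzchar(df$pfm_id[i])) df$pfm_id[i] else NULL)
  })
}

write_taxonomy <- function(tree, path) {
  write.table(data.frame(child = names(tree$parent), parent = unname(tree$parent)),
              path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages read their inputs from and write their artifacts to
#' `config$out_dir`:
#' \describe{
#'   \item{simulate}{writes `refs.tsv`, `queries.tsv`, `pfms.tsv`
#'     (canonical pfm-tsv, including held-out query truths),
#'     `taxonomy.tsv`.}
#'   \item{train}{assembles the per-superclass pair datasets and trains the
#'     SVR models; writes `model_sc<k>/` directories and `pairs_sc<k>.tsv`.}
#'   \item{predict}{transfers PFMs to every query; writes
#'     `predictions.tsv` and `predicted_pfms.tsv`.}
#'   \item{evaluate}{held-out regression report and framework comparison;
#'     writes `evaluation.json` and `comparison.tsv`.}
#'   \item{all}{all of the above in order.}
#' }
#'
#' @param config a [run_config()].
#' @param stage one of simulate, train, predict, evaluate, all.
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "train",
                                           "predict", "evaluate")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    run_pipeline(config, "simulate")
    run_pipeline(config, "train")
    run_pipeline(config, "predict")
    return(run_pipeline(config, "evaluate"))
  }
  out <- switch(stage,
                simulate = stage_simulate(config),
                train = stage_train(config),
                predict = stage_predict(config),
                evaluate = stage_evaluate(config))
  log_event(config, stage, "completed")
  invisible(out)
}

stage_simulate <- function(cfg) {
  params <- do.call(simulation_params, c(cfg$simulate, list(seed = cfg$seed)))
  corpus <- simulate_corpus(params)
  write_tf_table(corpus$refs, file.path(cfg$out_dir, "refs.tsv"))
  write_tf_table(corpus$queries, file.path(cfg$out_dir, "queries.tsv"))
  write_motifs(corpus$pfms, file.path(cfg$out_dir, "pfms.tsv"), "pfm-tsv")
  write_taxonomy(corpus$taxonomy, file.path(cfg$out_dir, "taxonomy.tsv"))
  corpus
}

load_corpus <- function(cfg) {
  pfms <- read_motifs(file.path(cfg$out_dir, "pfms.tsv"), "pfm-tsv")
  list(refs = read_tf_table(file.path(cfg$out_dir, "refs.tsv")),
       queries = read_tf_table(file.path(cfg$out_dir, "queries.tsv")),
       pfms = setNames(pfms, vapply(pfms, function(p) p$id, character(1))),
       taxonomy = read_taxonomy(file.path(cfg$out_dir, "taxonomy.tsv")))
}

corpus_superclasses <- function(tfs) {
  sort(unique(vapply(tfs, function(x) x$superclass, integer(1))))
}

stage_train <- function(cfg) {
  corpus <- load_corpus(cfg)
  fcfg <- feature_config_of(cfg)
  models <- list()
  for (sc in corpus_superclasses(corpus$refs)) {
    ds <- assemble_pair_dataset(corpus$refs, corpus$pfms, sc, fcfg,
                                corpus$taxonomy, seed = cfg$seed,
                                mosta_alpha = cfg$mosta_alpha)
    write.table(cbind(ds$pairs, ds$X),
                file.path(cfg$out_dir, sprintf("pairs_sc%d.tsv", sc)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    model <- train_superclass_model(ds, cfg$svr_grid, cfg$runs, cfg$folds,
                                    seed = cfg$seed)
    save_similarity_model(model, file.path(cfg$out_dir, sprintf("model_sc%d", sc)))
    models[[as.character(sc)]] <- model
  }
  models
}

# retrain deterministically from the persisted pair tables
load_models <- function(cfg, corpus) {
  fcfg <- feature_config_of(cfg)
  models <- list()
  for (sc in corpus_superclasses(corpus$refs)) {
    dir <- file.path(cfg$out_dir, sprintf("model_sc%d", sc))
    if (!dir.exists(dir)) next
    tab <- read.delim(file.path(cfg$out_dir, sprintf("pairs_sc%d.tsv", sc)))
    ds <- structure(list(superclass = sc,
                         pairs = tab[, c("acc_i", "acc_j", "label")],
                         X = as.matrix(tab[, FEATURE_IDS]),
                         labels = tab$label),
                    class = "pair_dataset")
    models[[as.character(sc)]] <- load_similarity_model(dir, ds)
  }
  models
}

stage_predict <- function(cfg) {
  corpus <- load_corpus(cfg)
  models <- load_models(cfg, corpus)
  fcfg <- feature_config_of(cfg)
  cache <- new_feature_cache()
  rows <- list()
  consensi <- list()
  for (q in corpus$queries) {
    model <- models[[as.character(q$superclass)]]
    if (is.null(model)) next
    tr <- transfer_pfm(q, corpus$refs, corpus$pfms, model, fcfg,
                       corpus$taxonomy, cfg$best_match, cfg$top_k,
                       cfg$outlier_ratio, cache, cfg$mosta_alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      query = q$accession, status = tr$status,
      n_candidates = nrow(tr$candidates),
      candidates = paste(tr$candidates$accession, collapse = ";"),
      predictions = paste(sprintf("%.4f", tr$candidates$pred), collapse = ";"),
      outliers_removed = paste(tr$outliers_removed, collapse = ";"))
    if (tr$status == "ok") consensi[[length(consensi) + 1L]] <- tr$consensus
  }
  write.table(do.call(rbind, rows), file.path(cfg$out_dir, "predictions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_motifs(consensi, file.path(cfg$out_dir, "predicted_pfms.tsv"), "pfm-tsv")
  list(predictions = do.call(rbind, rows), consensi = consensi)
}

stage_evaluate <- function(cfg) {
  corpus <- load_corpus(cfg)
  models <- load_models(cfg, corpus)
  fcfg <- feature_config_of(cfg)
  reports <- list()
  for (sc in names(models)) {
    test_ds <- try(assemble_pair_dataset(
      c(corpus$refs, corpus$queries), corpus$pfms, as.integer(sc), fcfg,
      corpus$taxonomy, seed = cfg$seed, mosta_alpha = cfg$mosta_alpha,
      panel = reference_panel(corpus$refs, as.integer(sc))),
      silent = TRUE)
    if (inherits(test_ds, "try-error")) next
    # held-out rows: pairs touching at least one query TF
    qacc <- vapply(corpus$queries, function(q) q$accession, character(1))
    keep <- test_ds$pairs$acc_i %in% qacc | test_ds$pairs$acc_j %in% qacc
    if (!any(keep)) next
    held <- structure(list(superclass = as.integer(sc),
                           pairs = test_ds$pairs[keep, ],
                           X = test_ds$X[keep, , drop = FALSE],
                           labels = test_ds$labels[keep]),
                      class = "pair_dataset")
    rep <- evaluate_similarity_model(models[[sc]], held)
    reports[[sc]] <- list(superclass = as.integer(sc), pearson_r = rep$pearson_r,
                          aae = rep$aae, n = rep$n)
  }
  cmp <- compare_frameworks(corpus$queries, corpus$refs, corpus$pfms, models,
                            fcfg, corpus$taxonomy, cfg$best_match, cfg$top_k,
                            cfg$outlier_ratio, seed = cfg$seed,
                            random_reps = cfg$random_reps,
                            mosta_alpha = cfg$mosta_alpha)
  write.table(cmp$per_query, file.path(cfg$out_dir, "comparison.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(regression = unname(reports),
         transfer = list(
           n_compared = nrow(cmp$per_query),
           aae_svr = mean(cmp$per_query$d_svr),
           aae_nn = mean(cmp$per_query$d_nn),
           aae_random = mean(cmp$per_query$d_random),
           transfer_rate = cmp$transfer_rate,
           sign_test_p_svr_vs_random = cmp$sign_test_p_svr_vs_random)),
    file.path(cfg$out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  list(regression = reports, comparison = cmp)
}
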