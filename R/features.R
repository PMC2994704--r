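# TF records and the 30-feature pairwise similarity battery.
#
# Features (ids f01..f30):
#   f01      sequence identity of the DBD alignment (BLOSUM62)
#   f02-f04  similarity fractions at thresholds d = 0, 1, 2 (BLOSUM62)
#   f05-f16  Needleman-Wunsch DBD scores under 12 substitution matrices
#   f17-f21  local alignment kernel under 5 matrices
#   f22-f24  mismatch kernels (3,1), (4,1), (5,1)
#   f25-f26  SVM-pairwise profile correlations (BLOSUM62, PAM70)
#   f27-f28  NW of the DBD flanking regions (f = 20, 50; N- and C-flank
#            scores summed)
#   f29      NW of predicted secondary structures of the whole proteins
#   f30      taxonomic similarity of the two species
#
# Every feature is normalized to [-1, 1] by the self-score rule
# 2*s(i,j)/(s(i,i)+s(j,j)); kernel-type features are already
# self-normalized, so the rule leaves them unchanged. When a TF has several
# DNA-binding domains, each domain-derived feature is the maximum of the
# normalized value over all domain pairs.

FEATURE_IDS <- sprintf("f%02d", 1:30)

#' Construct a transcription factor record
#'
#' @param accession unique identifier.
#' @param taxon species node name in the taxonomy.
#' @param superclass structural superclass, integer 1-5 (1 basic domain,
#'   2 zinc finger, 3 helix-turn-helix, 4 beta-scaffold, 5 others).
#' @param sequence amino-acid sequence of the whole protein.
#' @param dbd_intervals list of `c(start, end)` pairs (1-based inclusive)
#'   delimiting the DNA-binding domain(s).
#' @param ss_string optional precomputed secondary-structure string over
#'   `{H,E,C}`; predicted on demand when absent.
#' @param pfm_id optional identifier of the TF's PFM.
#' @return object of class `tf_record`.
#' @export
tf_record <- function(accession, taxon, superclass, sequence, dbd_intervals,
                      ss_string = NULL, pfm_id = NULL) {
  sequence <- sanitize_aa(sequence)
  if (!superclass %in% 1:5) stopf("TF '%s': superclass must be in 1..5", accession)
  if (is.numeric(dbd_intervals)) dbd_intervals <- list(dbd_intervals)
  if (length(dbd_intervals) == 0L) stopf("TF '%s': at least one DBD interval required", accession)
  n <- nchar(sequence)
  for (iv in dbd_intervals) {
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1L || iv[2] > n)
      stopf("TF '%s': invalid DBD interval [%s]", accession, paste(iv, collapse = ","))
  }
  dbd_seqs <- vapply(dbd_intervals, function(iv)
    substr(sequence, iv[1], iv[2]), character(1))
  structure(list(accession = as.character(accession), taxon = as.character(taxon),
                 superclass = as.integer(superclass), sequence = sequence,
                 dbd_intervals = lapply(dbd_intervals, as.integer),
                 dbd_seqs = dbd_seqs, ss_string = ss_string,
                 pfm_id = pfm_id),
            class = "tf_record")
}

#' @export
print.tf_record <- function(x, ...) {
  cat(sprintf("TF %s [superclass %d, %s]: %d aa, %d DBD(s)%s\n",
              x$accession, x$superclass, x$taxon, nchar(x$sequence),
              length(x$dbd_intervals),
              if (is.null(x$pfm_id)) "" else paste0(", PFM ", x$pfm_id)))
  invisible(x)
}

#' Feature configuration
#'
#' Default parameters of the 30-feature battery. All alignment parameters
#' and matrix assignments can be overridden; `matrices_dir` lets file-based
#' matrices stand in for any named matrix.
#'
#' @param ... overrides of the defaults (see source for names).
#' @return list of class `feature_config`.
#' @export
feature_config <- function(...) {
  cfg <- list(
    gap_open = 11, gap_extend = 1,
    sim_thresholds = c(0, 1, 2),
    nw_matrices = c("BLOSUM62", "PAM70", "PAM30", "CFHELIX", "CFSHEET",
                    "CFTURN", "KDHYDRO", "VOLUME", "PAM120", "PAM250",
                    "BLOSUM45", "BLOSUM80"),
    lak_matrices = c("BLOSUM62", "BLOSUM50", "PAM250", "KDHYDRO", "CFHELIX"),
    lak_beta = 0.5, lak_gap_open = 11, lak_gap_extend = 1,
    mismatch = list(c(3L, 1L), c(4L, 1L), c(5L, 1L)),
    profile_matrices = c("BLOSUM62", "PAM70"),
    flanks = c(20L, 50L),
    ss_gap_open = 4, ss_gap_extend = 1,
    matrices_dir = NULL,
    dbd_gate = 0.3)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown feature_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "feature_config")
}

#' Normalize a raw similarity score by its self scores
#'
#' `2*s(i,j) / (s(i,i) + s(j,j))`, clipped to `[-1, 1]`; `NA` (missing)
#' when the self-score sum is not positive.
#'
#' @param raw_ij raw pairwise score.
#' @param self_ii,self_jj self scores of the two objects.
#' @return normalized score in `[-1, 1]` or `NA`.
#' @export
normalize_feature <- function(raw_ij, self_ii, self_jj) {
  denom <- self_ii + self_jj
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  pmin(1, pmax(-1, 2 * raw_ij / denom))
}

#' Create a feature cache
#'
#' Environment reused across [compute_feature_vector()] calls on the same
#' corpus; caches per-TF self scores, secondary structures and
#' SVM-pairwise profile vectors.
#'
#' @return an environment.
#' @export
new_feature_cache <- function() new.env(parent = emptyenv())

cache_get <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (is.null(cache[[key]])) cache[[key]] <- compute()
  cache[[key]]
}

tf_ss <- function(tf, cache) {
  if (!is.null(tf$ss_string)) return(tf$ss_string)
  cache_get(cache, paste0("ss|", tf$accession),
            function() predict_secondary_structure(tf$sequence))
}

tf_flank <- function(tf, d, f) {
  iv <- tf$dbd_intervals[[d]]
  n <- nchar(tf$sequence)
  nfl <- substr(tf$sequence, max(1L, iv[1] - f), iv[1] - 1L)
  cfl <- substr(tf$sequence, iv[2] + 1L, min(n, iv[2] + f))
  list(n = nfl, c = cfl)
}

mx <- function(name, cfg) get_substitution_matrix(name, cfg$matrices_dir)

panel_signature <- function(panel) paste(names(panel), collapse = ",")

tf_profile_vector <- function(tf, d, mname, panel, cfg, cache) {
  cache_get(cache, paste(tf$accession, d, mname, "prof",
                         panel_signature(panel), sep = "|"), function() {
    m <- mx(mname, cfg)
    vapply(panel, function(p)
      nw_score(tf$dbd_seqs[d], p, m, cfg$gap_open, cfg$gap_extend),
      numeric(1))
  })
}

lak_self <- function(tf, d, mname, cfg, cache) {
  cache_get(cache, paste(tf$accession, d, mname, "lakself", sep = "|"), function() {
    ch <- strsplit(sanitize_aa(tf$dbd_seqs[d]), "")[[1]]
    lak_log_kernel(ch, ch, mx(mname, cfg), cfg$lak_beta,
                   cfg$lak_gap_open, cfg$lak_gap_extend)
  })
}

nw_self <- function(tf, d, mname, cfg, cache) {
  cache_get(cache, paste(tf$accession, d, mname, "self", sep = "|"),
            function() self_align_score(tf$dbd_seqs[d], mx(mname, cfg)))
}

# normalized feature value for one domain pair
domain_pair_features <- function(tfA, dA, tfB, dB, cfg, panel, cache) {
  sa <- tfA$dbd_seqs[dA]
  sb <- tfB$dbd_seqs[dB]
  out <- setNames(rep(NA_real_, 26L), FEATURE_IDS[1:26])
  # f01-f05: one BLOSUM62 alignment serves identity, similarity and score
  b62 <- mx("BLOSUM62", cfg)
  aln <- global_align(sa, sb, b62, cfg$gap_open, cfg$gap_extend,
                      sim_thresholds = cfg$sim_thresholds)
  out["f01"] <- normalize_feature(aln$identity, 1, 1)
  out[c("f02", "f03", "f04")] <- vapply(aln$similarity, normalize_feature,
                                        numeric(1), self_ii = 1, self_jj = 1)
  for (i in seq_along(cfg$nw_matrices)) {
    mname <- cfg$nw_matrices[i]
    sc <- if (i == 1L && mname == "BLOSUM62") aln$score
          else nw_score(sa, sb, mx(mname, cfg), cfg$gap_open, cfg$gap_extend)
    out[FEATURE_IDS[4L + i]] <- normalize_feature(
      sc, nw_self(tfA, dA, mname, cfg, cache), nw_self(tfB, dB, mname, cfg, cache))
  }
  chA <- strsplit(sa, "")[[1]]
  chB <- strsplit(sb, "")[[1]]
  for (i in seq_along(cfg$lak_matrices)) {
    mname <- cfg$lak_matrices[i]
    kxy <- lak_log_kernel(chA, chB, mx(mname, cfg), cfg$lak_beta,
                          cfg$lak_gap_open, cfg$lak_gap_extend)
    k <- exp(kxy - 0.5 * lak_self(tfA, dA, mname, cfg, cache)
                 - 0.5 * lak_self(tfB, dB, mname, cfg, cache))
    out[FEATURE_IDS[16L + i]] <- normalize_feature(k, 1, 1)
  }
  for (i in seq_along(cfg$mismatch)) {
    km <- cfg$mismatch[[i]]
    v <- mismatch_kernel(sa, sb, k = km[1], m = km[2])
    out[FEATURE_IDS[21L + i]] <- normalize_feature(v, 1, 1)
  }
  if (!is.null(panel)) {
    for (i in seq_along(cfg$profile_matrices)) {
      mname <- cfg$profile_matrices[i]
      va <- tf_profile_vector(tfA, dA, mname, panel, cfg, cache)
      vb <- tf_profile_vector(tfB, dB, mname, panel, cfg, cache)
      r <- suppressWarnings(profile_correlation(va, vb))
      out[FEATURE_IDS[24L + i]] <- if (is.na(r)) NA_real_ else normalize_feature(r, 1, 1)
    }
  }
  out
}

flank_feature <- function(tfA, dA, tfB, dB, f, cfg, cache) {
  b62 <- mx("BLOSUM62", cfg)
  fa <- tf_flank(tfA, dA, f)
  fb <- tf_flank(tfB, dB, f)
  sc <- 0
  self_a <- 0
  self_b <- 0
  for (side in c("n", "c")) {
    if (nzchar(fa[[side]]) && nzchar(fb[[side]]))
      sc <- sc + nw_score(fa[[side]], fb[[side]], b62,
                          cfg$gap_open, cfg$gap_extend)
    if (nzchar(fa[[side]])) self_a <- self_a + self_align_score(fa[[side]], b62)
    if (nzchar(fb[[side]])) self_b <- self_b + self_align_score(fb[[side]], b62)
  }
  normalize_feature(sc, self_a, self_b)
}

#' Compute the 30-feature vector of a TF pair
#'
#' All domain-derived features (f01-f26) take the maximum normalized value
#' over every pair of annotated DNA-binding domains. The SVM-pairwise
#' features (f25, f26) require a reference `panel`; the taxonomy feature
#' (f30) requires a `taxonomy` tree. Absent inputs flag the corresponding
#' features missing (`NA`).
#'
#' @param tfA,tfB `tf_record` objects.
#' @param config a [feature_config()].
#' @param panel named character vector of panel DBD sequences for the
#'   SVM-pairwise features (typically all reference TFs of the superclass,
#'   ordered by accession).
#' @param taxonomy optional `taxonomy_tree`.
#' @param cache optional [new_feature_cache()] shared across calls.
#' @return object of class `feature_vector`: named numeric vector field
#'   `normalized` (f01..f30, `NA` = missing) plus the `missing` flags.
#' @export
compute_feature_vector <- function(tfA, tfB, config = feature_config(),
                                   panel = NULL, taxonomy = NULL, cache = NULL) {
  stopifnot(inherits(tfA, "tf_record"), inherits(tfB, "tf_record"))
  if (!is.null(cache)) {  # all features are symmetric in (A, B)
    key <- paste0("fv|", paste(sort(c(tfA$accession, tfB$accession)), collapse = "|"),
                  "|", if (is.null(panel)) "" else panel_signature(panel))
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  vals <- setNames(rep(NA_real_, 30L), FEATURE_IDS)
  per_pair <- list()
  for (dA in seq_along(tfA$dbd_seqs)) for (dB in seq_along(tfB$dbd_seqs)) {
    per_pair[[length(per_pair) + 1L]] <-
      domain_pair_features(tfA, dA, tfB, dB, config, panel, cache)
  }
  dom <- do.call(rbind, per_pair)
  vals[FEATURE_IDS[1:26]] <- apply(dom, 2L, function(col)
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  for (i in seq_along(config$flanks)) {
    fl <- numeric(0)
    for (dA in seq_along(tfA$dbd_seqs)) for (dB in seq_along(tfB$dbd_seqs))
      fl <- c(fl, flank_feature(tfA, dA, tfB, dB, config$flanks[i], config, cache))
    vals[FEATURE_IDS[26L + i]] <- if (all(is.na(fl))) NA_real_ else max(fl, na.rm = TRUE)
  }
  ssA <- tf_ss(tfA, cache)
  ssB <- tf_ss(tfB, cache)
  ss_raw <- align_secondary_structure(ssA, ssB, config$ss_gap_open, config$ss_gap_extend)
  vals["f29"] <- normalize_feature(ss_raw, 2 * nchar(ssA), 2 * nchar(ssB))
  if (!is.null(taxonomy)) {
    tx <- suppressWarnings(taxonomy_similarity(tfA$taxon, tfB$taxon, taxonomy))
    vals["f30"] <- if (is.na(tx)) NA_real_ else normalize_feature(tx, 1, 1)
  }
  fv <- structure(list(normalized = vals, missing = is.na(vals)),
                  class = "feature_vector")
  if (!is.null(cache)) cache[[key]] <- fv
  fv
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("feature vector (normalized):\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' DBD similarity gate between two TFs
#'
#' Normalized BLOSUM62 Needleman-Wunsch score of the DNA-binding domains
#' (maximum over domain pairs). Pairs above `config$dbd_gate` (default 0.3)
#' are "local TF-pairs", eligible for training and candidate matching.
#'
#' @inheritParams compute_feature_vector
#' @return normalized score in `[-1, 1]`.
#' @export
dbd_similarity <- function(tfA, tfB, config = feature_config(), cache = NULL) {
  key <- paste0("gate|", paste(sort(c(tfA$accession, tfB$accession)), collapse = "|"))
  cache_get(cache, key, function() {
    b62 <- mx("BLOSUM62", config)
    best <- -Inf
    for (dA in seq_along(tfA$dbd_seqs)) for (dB in seq_along(tfB$dbd_seqs)) {
      sc <- nw_score(tfA$dbd_seqs[dA], tfB$dbd_seqs[dB], b62,
                     config$gap_open, config$gap_extend)
      v <- normalize_feature(sc, nw_self(tfA, dA, "BLOSUM62", config, cache),
                             nw_self(tfB, dB, "BLOSUM62", config, cache))
      if (!is.na(v) && v > best) best <- v
    }
    best
  })
}

#' Default SVM-pairwise panel for a reference set
#'
#' First DBD sequence of every reference TF of the given superclass,
#' ordered deterministically by accession.
#'
#' @param refs list of `tf_record`s.
#' @param superclass integer 1-5.
#' @return named character vector of DBD sequences.
#' @export
reference_panel <- function(refs, superclass) {
  refs <- Filter(function(tf) tf$superclass == superclass, refs)
  refs <- refs[order(vapply(refs, function(tf) tf$accession, character(1)))]
  setNames(vapply(refs, function(tf) tf$dbd_seqs[1], character(1)),
           vapply(refs, function(tf) tf$accession, character(1)))
}
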