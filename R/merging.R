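# Ungapped PFM alignment and progressive merging into a consensus
# (familial-binding-profile style), also used to collapse several PFMs
# annotated to one TF.
#
# Columns are compared by the Pearson correlation of their frequency
# vectors (zero-variance columns, e.g. uniform padding, correlate 0 by
# convention); an alignment score sums, over the overlap, the column
# correlation plus an extension bonus of 0.5, so that lengthening an
# alignment by a moderately matching column always beats shortening the
# overlap to a single perfectly correlated edge column. Merging is guided
# by a UPGMA tree on pairwise alignment
# distances; aligned columns are averaged with weights proportional to each
# matrix's source_count, and columns covered by less than half of the
# contributing weight are trimmed from the ends.

column_correlation <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

COLUMN_BONUS <- 0.5  # per aligned column, added to the correlation

# offset convention: B's first column sits at A-coordinate offset + 1
alignment_score_at <- function(mA, mB, offset) {
  LA <- ncol(mA)
  LB <- ncol(mB)
  i1 <- max(1L, offset + 1L)
  i2 <- min(LA, offset + LB)
  if (i2 < i1) return(NULL)
  sc <- vapply(i1:i2, function(i)
    column_correlation(mA[, i], mB[, i - offset]), numeric(1))
  list(score = sum(sc + COLUMN_BONUS), n_overlap = i2 - i1 + 1L,
       corr_sum = sum(sc))
}

#' Ungapped alignment of two PFMs
#'
#' Finds the offset and orientation maximizing the sum of per-column
#' Pearson correlations between overlapping frequency columns. Ties are
#' broken by smaller absolute offset, then by the sense orientation. The
#' offset places B's first column at A-coordinate `offset + 1`.
#'
#' @param a,b `pfm` objects.
#' @return object of class `pfm_alignment`: `offset`, `orientation`,
#'   `score` (with the extension bonus), `corr_sum` (plain correlation
#'   sum), `n_overlap`.
#' @export
align_pfms_ungapped <- function(a, b) {
  validate_pfm(a)
  validate_pfm(b)
  mA <- a$matrix
  variants <- list(sense = b$matrix, antisense = pfm_revcomp(b)$matrix)
  best <- NULL
  for (orient in c("sense", "antisense")) {
    mB <- variants[[orient]]
    for (offset in (-(ncol(mB) - 1L)):(ncol(mA) - 1L)) {
      al <- alignment_score_at(mA, mB, offset)
      if (is.null(al)) next
      cand <- list(offset = offset, orientation = orient,
                   score = al$score, n_overlap = al$n_overlap,
                   corr_sum = al$corr_sum)
      if (is.null(best) || cand$score > best$score + 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           (abs(cand$offset) < abs(best$offset) ||
            (abs(cand$offset) == abs(best$offset) && orient == "sense" &&
             best$orientation == "antisense")))) best <- cand
    }
  }
  structure(best, class = "pfm_alignment")
}

#' @export
print.pfm_alignment <- function(x, ...) {
  cat(sprintf("PFM alignment: offset %d, %s, score %.3f over %d column(s)\n",
              x$offset, x$orientation, x$score, x$n_overlap))
  invisible(x)
}

# internal running profile: weight-summed frequencies + per-column weight
profile_of <- function(x, weight) {
  list(freqsum = x$matrix * weight, cov = rep(weight, ncol(x$matrix)))
}

profile_pfm <- function(pr, id = "profile") {
  pfm(sweep(pr$freqsum, 2L, pr$cov, "/"), id = id)
}

profile_revcomp <- function(pr) {
  list(freqsum = pr$freqsum[c(4, 3, 2, 1), rev(seq_len(ncol(pr$freqsum))), drop = FALSE],
       cov = rev(pr$cov))
}

merge_profiles <- function(pa, pb) {
  al <- align_pfms_ungapped(profile_pfm(pa), profile_pfm(pb))
  if (al$orientation == "antisense") pb <- profile_revcomp(pb)
  LA <- ncol(pa$freqsum)
  LB <- ncol(pb$freqsum)
  lo <- min(1L, al$offset + 1L)
  hi <- max(LA, al$offset + LB)
  n <- hi - lo + 1L
  fs <- matrix(0, 4L, n)
  cv <- numeric(n)
  ia <- (1L:LA) - lo + 1L
  ib <- (al$offset + 1L):(al$offset + LB) - lo + 1L
  fs[, ia] <- fs[, ia] + pa$freqsum
  cv[ia] <- cv[ia] + pa$cov
  fs[, ib] <- fs[, ib] + pb$freqsum
  cv[ib] <- cv[ib] + pb$cov
  list(freqsum = fs, cov = cv)
}

#' Merge PFMs into a consensus
#'
#' A single PFM is returned unchanged. Otherwise a UPGMA guide tree on
#' pairwise ungapped-alignment distances orders a progressive merge;
#' aligned columns are averaged with weights proportional to each input's
#' `source_count` (overridable via `weights`), and edge columns carried by
#' less than `min_coverage` of the total weight are trimmed.
#'
#' @param pfms nonempty list of `pfm` objects.
#' @param weights optional numeric weights (default: `source_count`s).
#' @param min_coverage trim fraction threshold (default 0.5).
#' @param id identifier of the consensus.
#' @return the consensus `pfm`; its `source_count` is the summed weight.
#' @export
merge_pfms <- function(pfms, weights = NULL, min_coverage = 0.5, id = "consensus") {
  if (length(pfms) == 0L) stopf("merge_pfms: empty PFM list")
  if (is.null(weights))
    weights <- vapply(pfms, function(p) as.numeric(p$source_count), numeric(1))
  if (length(pfms) == 1L) return(pfms[[1L]])
  profiles <- Map(profile_of, pfms, weights)
  if (length(profiles) == 2L) {
    merged <- merge_profiles(profiles[[1L]], profiles[[2L]])
  } else {
    n <- length(profiles)
    D <- matrix(0, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      al <- align_pfms_ungapped(pfms[[i]], pfms[[j]])
      D[i, j] <- D[j, i] <- 1 - al$corr_sum / al$n_overlap  # mean column corr -> [0,2]
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1L)
    grab <- function(k) if (k < 0) profiles[[-k]] else nodes[[k]]
    for (r in seq_len(nrow(hc$merge))) {
      nodes[[r]] <- merge_profiles(grab(hc$merge[r, 1L]), grab(hc$merge[r, 2L]))
    }
    merged <- nodes[[n - 1L]]
  }
  total <- sum(weights)
  keep <- merged$cov >= min_coverage * total - 1e-9
  if (any(keep)) {
    lo <- min(which(keep))
    hi <- max(which(keep))
  } else {  # degenerate: retain the best-covered column
    lo <- hi <- which.max(merged$cov)
  }
  out <- pfm(sweep(merged$freqsum[, lo:hi, drop = FALSE], 2L,
                   merged$cov[lo:hi], "/"), id = id)
  out$source_count <- as.integer(round(total))
  out
}

#' Collapse several PFMs annotated to one TF
#'
#' Thin wrapper around [merge_pfms()]: whenever a TF carries multiple
#' experimentally derived matrices they are merged into one consensus
#' before entering the reference set.
#'
#' @inheritParams merge_pfms
#' @return the consensus `pfm`.
#' @export
collapse_tf_pfms <- function(pfms, id = "consensus") merge_pfms(pfms, id = id)
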