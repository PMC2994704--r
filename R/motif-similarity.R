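# PFM similarity in overlap-probability ("MoSta") units.
#
# Each PFM is turned into a calibrated hit model: a log-odds scoring matrix
# plus a score cutoff chosen so that the probability p of a hit at a fixed
# position of an i.i.d. background sequence is at most a configured type-I
# rate alpha. The similarity of two PFMs is the probability gamma that both
# produce a hit at a fixed relative offset, divided by the product of the
# individual hit probabilities, maximized over all overlapping offsets and
# both orientations. Self-similarity is 1/p, and the arithmetic-mean
# normalization 2*Smax(A,B)/(Smax(A,A)+Smax(B,B)) maps the score to [0,1];
# distance d = 1 - s_norm.
#
# Score distributions are computed exactly by convolving per-position score
# tables (outer sums) whenever the word space involved is small, and by a
# discretized-grid dynamic program (step `step` on the log-odds scale)
# otherwise. The background is assumed strand-symmetric when the antisense
# orientation is evaluated.

HIT_TOL <- 1e-9

# log2 odds scores with pseudocount smoothing: finite for zero frequencies
pfm_scores <- function(x, background, pseudocount) {
  f <- (x$matrix + pseudocount * background) / (1 + pseudocount)
  log2(f / background)
}

# exact distribution of the summed score over `cols` (outer-sum convolution);
# values are not aggregated (survival queries sort them anyway)
dist_exact <- function(scores, bg, cols) {
  vals <- 0
  prb <- 1
  for (j in cols) {
    vals <- as.vector(outer(vals, scores[, j], "+"))
    prb <- as.vector(outer(prb, bg, "*"))
  }
  list(values = vals, probs = prb)
}

# grid DP with integer-scaled scores; returns achievable grid values + probs
dist_grid <- function(scores, bg, cols, step) {
  if (length(cols) == 0L) return(list(values = 0, probs = 1))
  k <- round(scores[, cols, drop = FALSE] / step)
  lo <- sum(apply(k, 2, min))
  hi <- sum(apply(k, 2, max))
  nb <- hi - lo + 1L
  p <- numeric(nb)
  off <- 0L
  p[1L] <- 1  # running distribution over (current sum - running minimum)
  cur <- 1L
  for (jj in seq_len(ncol(k))) {
    cmin <- min(k[, jj])
    newlen <- cur + (max(k[, jj]) - cmin)
    np <- numeric(newlen)
    for (b in 1:4) {
      sh <- k[b, jj] - cmin
      idx <- seq_len(cur) + sh
      np[idx] <- np[idx] + p[seq_len(cur)] * bg[b]
    }
    p <- np
    cur <- newlen
  }
  keep <- p > 0
  list(values = (lo + (which(keep) - 1L)) * step, probs = p[keep])
}

dist_over <- function(scores, bg, cols, step, exact_cap) {
  if (length(cols) == 0L) return(list(values = 0, probs = 1))
  if (length(cols) <= exact_cap) dist_exact(scores, bg, cols)
  else dist_grid(scores, bg, cols, step)
}

# survival function P(X >= r - tol) for a value/prob table, vectorized in r
make_survival <- function(dist) {
  o <- order(dist$values)
  v <- dist$values[o]
  tailp <- rev(cumsum(rev(dist$probs[o])))
  n <- length(v)
  function(r) {
    cnt_lt <- findInterval(r - HIT_TOL, v, left.open = TRUE)
    out <- numeric(length(r))
    hit <- cnt_lt < n
    out[hit] <- tailp[cnt_lt[hit] + 1L]
    out
  }
}

#' Calibrate a hit model for a PFM
#'
#' Converts a PFM to a log-odds scoring matrix against an i.i.d. background
#' and selects the smallest achievable score cutoff `threshold` such that
#' the probability of a hit at a fixed background position is at most
#' `alpha`. The attained probability `p` is computed exactly from the score
#' distribution (outer-sum convolution for motifs up to `exact_cap`
#' positions, discretized-grid dynamic program with resolution `step`
#' otherwise).
#'
#' @param x a `pfm`.
#' @param background length-4 background probabilities (A,C,G,T).
#' @param alpha per-position type-I rate in (0,1).
#' @param pseudocount pseudocount mixed into frequencies before the log.
#' @param step grid resolution (log-odds units) for long motifs.
#' @param exact_cap maximum number of positions handled by exact convolution.
#' @return an object of class `hit_model` with elements `scores`,
#'   `threshold`, `p`, `alpha`, `background`.
#' @export
calibrate_hit_model <- function(x, background = rep(0.25, 4), alpha = 1e-3,
                                pseudocount = 0.01, step = 1e-3, exact_cap = 8L) {
  validate_pfm(x)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0,1)")
  background <- check_background(background)
  scores <- pfm_scores(x, background, pseudocount)
  L <- ncol(scores)
  d <- dist_over(scores, background, seq_len(L), step, exact_cap)
  # group achievable scores (descending) and accumulate tail probability
  o <- order(d$values, decreasing = TRUE)
  v <- d$values[o]
  p <- d$probs[o]
  grp <- cumsum(c(TRUE, diff(v) < -HIT_TOL))
  gv <- tapply(v, grp, max)
  gp <- tapply(p, grp, sum)
  cum <- cumsum(gp)
  ok <- which(cum <= alpha + HIT_TOL)
  if (length(ok) == 0L) {
    warnf("PFM '%s': alpha=%.3g below probability of the best word; cutoff set to max score",
          x$id, alpha)
    threshold <- gv[[1L]]
    hp <- cum[[1L]]
  } else {
    k <- max(ok)
    threshold <- gv[[k]]
    hp <- cum[[k]]
  }
  structure(list(id = x$id, pfm = x, scores = scores, threshold = as.numeric(threshold),
                 p = as.numeric(hp), alpha = alpha, background = background,
                 pseudocount = pseudocount, step = step, exact_cap = as.integer(exact_cap)),
            class = "hit_model")
}

#' @export
print.hit_model <- function(x, ...) {
  cat(sprintf("hit model '%s': L=%d, threshold=%.4f, p=%.3g (alpha=%.3g)\n",
              x$id, ncol(x$scores), x$threshold, x$p, x$alpha))
  invisible(x)
}

# hit model of the reverse complement, sharing the calibrated threshold
hit_model_revcomp <- function(hm) {
  sc <- hm$scores[c(4, 3, 2, 1), rev(seq_len(ncol(hm$scores))), drop = FALSE]
  rownames(sc) <- DNA_BASES
  out <- hm
  out$id <- paste0(hm$id, "_rc")
  out$scores <- sc
  out
}

as_hit_model <- function(x, ...) {
  if (inherits(x, "hit_model")) x else calibrate_hit_model(x, ...)
}

# memoised calibration keyed by matrix content; calibration is pure, and
# the same reference PFMs recur throughout training and evaluation
hit_model_env <- new.env(parent = emptyenv())

hit_model_memo <- function(x, alpha = 1e-3) {
  if (inherits(x, "hit_model")) return(x)
  key <- paste(x$id, alpha, paste(format(c(x$matrix), digits = 15), collapse = ","),
               sep = "|")
  if (is.null(hit_model_env[[key]])) {
    hm <- suppressWarnings(calibrate_hit_model(x, alpha = alpha))
    attr(hm, "memo_key") <- key
    hit_model_env[[key]] <- hm
  }
  hit_model_env[[key]]
}

# memoised s_norm for hit models created through hit_model_memo
smax_memo_env <- new.env(parent = emptyenv())

smax_memo <- function(hmA, hmB) {
  ka <- attr(hmA, "memo_key")
  kb <- attr(hmB, "memo_key")
  if (is.null(ka) || is.null(kb)) return(smax(hmA, hmB))
  key <- paste(sort(c(ka, kb)), collapse = "$")
  if (is.null(smax_memo_env[[key]])) smax_memo_env[[key]] <- smax(hmA, hmB)
  smax_memo_env[[key]]
}

overlap_window <- function(hmA, hmB, offset) {
  LA <- ncol(hmA$scores)
  LB <- ncol(hmB$scores)
  if (offset < -(LB - 1L) || offset > LA - 1L)
    stopf("offset %d outside overlapping range [%d, %d]", offset, -(LB - 1L), LA - 1L)
  i1 <- max(1L, offset + 1L)
  i2 <- min(LA, offset + LB)
  list(i1 = i1, i2 = i2, a_cols = i1:i2, b_cols = (i1:i2) - offset,
       a_out = setdiff(seq_len(LA), i1:i2), b_out = setdiff(seq_len(LB), (i1:i2) - offset))
}

# joint distribution of (overlap score of A, overlap score of B) over the
# shared word: exact enumeration for small windows, 2-D grid DP otherwise
joint_overlap_dist <- function(hmA, hmB, win, exact_cap, step) {
  v <- length(win$a_cols)
  bg <- hmA$background
  if (v <= exact_cap) {
    sa <- 0; sb <- 0; pw <- 1
    for (j in seq_len(v)) {
      sa <- as.vector(outer(sa, hmA$scores[, win$a_cols[j]], "+"))
      sb <- as.vector(outer(sb, hmB$scores[, win$b_cols[j]], "+"))
      pw <- as.vector(outer(pw, bg, "*"))
    }
    return(list(sa = sa, sb = sb, pw = pw))
  }
  # 2-D grid DP, resolution coarsened so each axis stays below ~1500 bins
  rngA <- sum(apply(hmA$scores[, win$a_cols, drop = FALSE], 2, max) -
                apply(hmA$scores[, win$a_cols, drop = FALSE], 2, min))
  rngB <- sum(apply(hmB$scores[, win$b_cols, drop = FALSE], 2, max) -
                apply(hmB$scores[, win$b_cols, drop = FALSE], 2, min))
  stepA <- max(step, rngA / 1500)
  stepB <- max(step, rngB / 1500)
  kA <- round(hmA$scores[, win$a_cols, drop = FALSE] / stepA)
  kB <- round(hmB$scores[, win$b_cols, drop = FALSE] / stepB)
  loA <- sum(apply(kA, 2, min)); loB <- sum(apply(kB, 2, min))
  nA <- sum(apply(kA, 2, max)) - loA + 1L
  nB <- sum(apply(kB, 2, max)) - loB + 1L
  P <- matrix(0, nA, nB)
  P[1L, 1L] <- 1
  curA <- 1L; curB <- 1L
  for (j in seq_len(v)) {
    cminA <- min(kA[, j]); cminB <- min(kB[, j])
    newA <- curA + max(kA[, j]) - cminA
    newB <- curB + max(kB[, j]) - cminB
    NP <- matrix(0, newA, newB)
    for (b in 1:4) {
      shA <- kA[b, j] - cminA
      shB <- kB[b, j] - cminB
      NP[seq_len(curA) + shA, seq_len(curB) + shB] <-
        NP[seq_len(curA) + shA, seq_len(curB) + shB] + P[seq_len(curA), seq_len(curB)] * bg[b]
    }
    P <- NP; curA <- newA; curB <- newB
  }
  nz <- which(P > 0, arr.ind = TRUE)
  list(sa = (loA + nz[, 1] - 1L) * stepA,
       sb = (loB + nz[, 2] - 1L) * stepB,
       pw = P[nz])
}

gamma_factorized <- function(hmA, hmB, offset) {
  win <- overlap_window(hmA, hmB, offset)
  jd <- joint_overlap_dist(hmA, hmB, win, hmA$exact_cap, hmA$step)
  survA <- make_survival(dist_over(hmA$scores, hmA$background, win$a_out,
                                   hmA$step, hmA$exact_cap))
  survB <- make_survival(dist_over(hmB$scores, hmB$background, win$b_out,
                                   hmB$step, hmB$exact_cap))
  sum(jd$pw * survA(hmA$threshold - jd$sa) * survB(hmB$threshold - jd$sb))
}

gamma_enumerate <- function(hmA, hmB, offset, cap = 12L) {
  win <- overlap_window(hmA, hmB, offset)
  LA <- ncol(hmA$scores)
  LB <- ncol(hmB$scores)
  u1 <- min(1L, offset + 1L)
  u2 <- max(LA, offset + LB)
  U <- u2 - u1 + 1L
  if (U > cap) stopf("union window %d exceeds enumeration cap %d", U, cap)
  bg <- hmA$background
  sa <- 0; sb <- 0; pw <- 1
  for (pos in u1:u2) {
    inA <- pos >= 1L && pos <= LA
    inB <- pos - offset >= 1L && pos - offset <= LB
    sa <- as.vector(outer(sa, if (inA) hmA$scores[, pos] else numeric(4), "+"))
    sb <- as.vector(outer(sb, if (inB) hmB$scores[, pos - offset] else numeric(4), "+"))
    pw <- as.vector(outer(pw, bg, "*"))
  }
  sum(pw[sa >= hmA$threshold - HIT_TOL & sb >= hmB$threshold - HIT_TOL])
}

#' Joint hit probability of two calibrated PFMs at a fixed offset
#'
#' Probability, under the i.i.d. background, that matrix A produces a hit at
#' some position x and matrix B (or its reverse complement) produces a hit
#' at x + `offset`. Positions outside the overlap contribute independently
#' given the shared overlap word, so the computation factorizes exactly into
#' the joint overlap-score distribution and the two out-of-overlap survival
#' functions (`method = "dp"`). `method = "enumerate"` scores every word of
#' the union window instead and is intended for cross-checks on short
#' motifs.
#'
#' @param hmA,hmB `hit_model` objects (see [calibrate_hit_model()]), or
#'   `pfm` objects to be calibrated with defaults.
#' @param offset integer offset of B relative to A, within
#'   `[-(L_B-1), L_A-1]`.
#' @param orientation `"sense"` or `"antisense"` (B reverse-complemented).
#' @param method `"dp"` (default) or `"enumerate"`.
#' @return the joint probability gamma, a number in `[0, min(p_A, p_B)]`.
#' @export
overlap_probability <- function(hmA, hmB, offset,
                                orientation = c("sense", "antisense"),
                                method = c("dp", "enumerate")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  hmA <- as_hit_model(hmA)
  hmB <- as_hit_model(hmB)
  if (orientation == "antisense") hmB <- hit_model_revcomp(hmB)
  if (method == "dp") gamma_factorized(hmA, hmB, offset)
  else gamma_enumerate(hmA, hmB, offset)
}

#' Maximum overlap similarity of two PFMs
#'
#' Computes `Smax`: the joint hit probability divided by the product of the
#' individual hit probabilities, maximized over all overlapping offsets and
#' both orientations. The normalized score
#' `s_norm = 2*Smax(A,B) / (Smax(A,A) + Smax(B,B))` lies in `[0,1]` and the
#' distance is `d = 1 - s_norm`. Self-similarity `Smax(A,A)` equals `1/p_A`.
#'
#' @inheritParams calibrate_hit_model
#' @param a,b `pfm` or `hit_model` objects.
#' @param method passed to [overlap_probability()].
#' @return an object of class `similarity_score`: list with `smax_raw`,
#'   `s_norm`, `d`, `best_offset`, `best_orientation`, `p_A`, `p_B`.
#' @export
smax <- function(a, b, background = rep(0.25, 4), alpha = 1e-3,
                 pseudocount = 0.01, step = 1e-3, exact_cap = 8L,
                 method = c("dp", "enumerate")) {
  method <- match.arg(method)
  hmA <- as_hit_model(a, background = background, alpha = alpha,
                      pseudocount = pseudocount, step = step, exact_cap = exact_cap)
  hmB <- as_hit_model(b, background = background, alpha = alpha,
                      pseudocount = pseudocount, step = step, exact_cap = exact_cap)
  LA <- ncol(hmA$scores)
  LB <- ncol(hmB$scores)
  hmBrc <- hit_model_revcomp(hmB)
  best <- list(val = -Inf, offset = 0L, orientation = "sense")
  for (orient in c("sense", "antisense")) {
    hb <- if (orient == "sense") hmB else hmBrc
    for (s in (-(LB - 1L)):(LA - 1L)) {
      g <- if (method == "dp") gamma_factorized(hmA, hb, s) else gamma_enumerate(hmA, hb, s)
      val <- g / (hmA$p * hmB$p)
      better <- val > best$val + 1e-12 ||
        (abs(val - best$val) <= 1e-12 &&
           (abs(s) < abs(best$offset) ||
              (abs(s) == abs(best$offset) && orient == "sense" &&
                 best$orientation == "antisense")))
      if (better) best <- list(val = val, offset = s, orientation = orient)
    }
  }
  self_sum <- 1 / hmA$p + 1 / hmB$p
  s_norm <- clip01(2 * best$val / self_sum)
  structure(list(smax_raw = best$val, s_norm = s_norm, d = 1 - s_norm,
                 best_offset = best$offset, best_orientation = best$orientation,
                 p_A = hmA$p, p_B = hmB$p),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("s_norm=%.4f (d=%.4f), Smax=%.3g, offset=%d, %s\n",
              x$s_norm, x$d, x$smax_raw, x$best_offset, x$best_orientation))
  invisible(x)
}

#' Normalized overlap distance between two PFMs
#'
#' Convenience wrapper around [smax()] returning only `d = 1 - s_norm`.
#'
#' @inheritParams smax
#' @return distance in `[0,1]`.
#' @export
pfm_distance <- function(a, b, ...) smax(a, b, ...)$d

#' Pairwise similarity matrix for a set of PFMs
#'
#' Computes `s_norm` for every pair, calibrating each hit model once.
#'
#' @param pfms list of `pfm` objects.
#' @inheritParams calibrate_hit_model
#' @return symmetric matrix of normalized similarities with unit diagonal.
#' @export
pfm_similarity_matrix <- function(pfms, background = rep(0.25, 4), alpha = 1e-3,
                                  pseudocount = 0.01, step = 1e-3, exact_cap = 8L) {
  n <- length(pfms)
  hms <- lapply(pfms, calibrate_hit_model, background = background, alpha = alpha,
                pseudocount = pseudocount, step = step, exact_cap = exact_cap)
  S <- diag(1, n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- smax(hms[[i]], hms[[j]])$s_norm
    }
  }
  ids <- vapply(pfms, function(p) p$id, character(1))
  dimnames(S) <- list(ids, ids)
  S
}
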