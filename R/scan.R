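# Minimal weight-score promoter scanner.
#
# Predicted PFMs are converted to log2 weight matrices; the weight score of
# a window is the summed log2 ratio of the (pseudocount-smoothed) matrix
# probability to the background probability of each nucleotide. Per-matrix
# cutoffs follow the "minimization of false positives" strategy: the
# smallest cutoff whose hit probability under the background is at most
# alpha, computed exactly for order-0 backgrounds and empirically on
# simulated background sequence for higher-order Markov backgrounds.

#' Background sequence model
#'
#' Order-0 (i.i.d.) or order-kappa Markov model over A,C,G,T.
#'
#' @param probs length-4 stationary/initial probabilities.
#' @param order Markov order kappa (default 0).
#' @param trans for `order >= 1`, a `4^order x 4` row-stochastic matrix of
#'   transition probabilities, rows indexed by the lexicographic context.
#' @return object of class `background_model`.
#' @export
background_model <- function(probs = rep(0.25, 4), order = 0L, trans = NULL) {
  probs <- check_background(probs)
  order <- as.integer(order)
  if (order > 0L) {
    if (is.null(trans) || !all(dim(trans) == c(4L^order, 4L)))
      stopf("order-%d model needs a %d x 4 transition matrix", order, 4L^order)
    trans <- sweep(trans, 1L, rowSums(trans), "/")
  }
  structure(list(probs = probs, order = order, trans = trans),
            class = "background_model")
}

#' Train a background model from sequences
#'
#' Maximum-likelihood base and k-mer context transition frequencies with
#' add-one smoothing.
#'
#' @param sequences character vector of DNA sequences (or a FASTA path).
#' @param order Markov order.
#' @return a `background_model`.
#' @export
train_background_model <- function(sequences, order = 0L) {
  if (length(sequences) == 1L && file.exists(sequences))
    sequences <- as.character(Biostrings::readDNAStringSet(sequences))
  codes <- unlist(lapply(sequences, encode_dna))
  counts <- tabulate(codes, 4L) + 1
  probs <- counts / sum(counts)
  if (order == 0L) return(background_model(probs, 0L))
  n_ctx <- 4L^order
  trans <- matrix(1, n_ctx, 4L)
  for (seq in sequences) {
    v <- encode_dna(seq)
    if (length(v) <= order) next
    ctx <- context_index(v, order)
    pos <- (order + 1L):length(v)
    for (t in seq_along(pos))
      trans[ctx[t], v[pos[t]]] <- trans[ctx[t], v[pos[t]]] + 1
  }
  background_model(probs, order, trans)
}

encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (anyNA(v)) stopf("non-ACGT character in DNA sequence")
  v
}

# lexicographic index of the length-`order` context ending just before each
# position order+1 .. n
context_index <- function(v, order) {
  n <- length(v)
  idx <- rep(1L, n - order)
  for (j in seq_len(order))
    idx <- idx + (v[(order - j + 1L):(n - j)] - 1L) * 4L^(j - 1L)
  idx
}

#' Convert a PFM to a scoring weight matrix
#'
#' Entries are `log2(((f + pseudocount*bg) / (1 + pseudocount)) / bg)`,
#' finite for zero frequencies whenever `pseudocount > 0`.
#'
#' @param x a `pfm`.
#' @param background length-4 background probabilities.
#' @param pseudocount smoothing pseudocount (default 0.01).
#' @return object of class `pwm` with fields `matrix` (log-odds),
#'   `logfreq` (log2 smoothed frequencies), `background`, `pseudocount`.
#' @export
pfm_to_scoring_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.01) {
  validate_pfm(x)
  background <- check_background(background)
  f <- (x$matrix + pseudocount * background) / (1 + pseudocount)
  if (any(f <= 0)) stopf("PFM '%s': zero frequency with zero pseudocount", x$id)
  structure(list(id = x$id, matrix = log2(f / background), logfreq = log2(f),
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (length %d, pseudocount %g)\n",
              x$id, ncol(x$matrix), x$pseudocount))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Weight score of a subsequence under a PWM
#'
#' Summed per-position `log2(p_matrix / p_background)`. With the default
#' `bg_model = NULL` the PWM's own (order-0) background applies; an
#' order-kappa `background_model` replaces the denominator by contextual
#' probabilities (positions without full context fall back to the
#' stationary base probabilities).
#'
#' @param pwm a `pwm`.
#' @param subsequence DNA string of the motif length.
#' @param bg_model optional `background_model`.
#' @return the weight score (log2 units).
#' @export
weight_score <- function(pwm, subsequence, bg_model = NULL) {
  v <- encode_dna(subsequence)
  L <- ncol(pwm$matrix)
  if (length(v) != L) stopf("subsequence length %d != motif length %d", length(v), L)
  if (is.null(bg_model) || bg_model$order == 0L) {
    probs <- if (is.null(bg_model)) pwm$background else bg_model$probs
    return(sum(pwm$logfreq[cbind(v, seq_len(L))] - log2(probs[v])))
  }
  lp_bg <- numeric(L)
  ord <- bg_model$order
  for (i in seq_len(L)) {
    lp_bg[i] <- if (i <= ord) log2(bg_model$probs[v[i]])
    else log2(bg_model$trans[context_index(v[(i - ord):i], ord), v[i]])
  }
  sum(pwm$logfreq[cbind(v, seq_len(L))]) - sum(lp_bg)
}

#' Calibrate a per-matrix weight-score cutoff
#'
#' "Minimization of false positives": the smallest achievable cutoff whose
#' hit probability under the background model is at most `alpha`. Exact by
#' score-distribution convolution for order-0 backgrounds; for
#' `order >= 1` the cutoff is set empirically on `sim_length` bases of
#' simulated background sequence.
#'
#' @param pwm a `pwm`.
#' @param bg_model optional `background_model` (default: the PWM's own).
#' @param alpha per-window type-I rate (default 1e-3).
#' @param sim_length simulated background length for Markov calibration.
#' @param seed seed for the simulation.
#' @return list with `cutoff` and the attained `hit_prob`.
#' @export
calibrate_cutoff <- function(pwm, bg_model = NULL, alpha = 1e-3,
                             sim_length = 1e5, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  L <- ncol(pwm$matrix)
  if (is.null(bg_model) || bg_model$order == 0L) {
    probs <- if (is.null(bg_model)) pwm$background else bg_model$probs
    scores <- sweep(pwm$logfreq, 1L, log2(probs), "-")
    d <- dist_over(scores, probs, seq_len(L), step = 1e-3, exact_cap = 8L)
    o <- order(d$values, decreasing = TRUE)
    v <- d$values[o]
    p <- d$probs[o]
    grp <- cumsum(c(TRUE, diff(v) < -HIT_TOL))
    gv <- tapply(v, grp, max)
    cum <- cumsum(tapply(p, grp, sum))
    ok <- which(cum <= alpha + HIT_TOL)
    if (length(ok) == 0L)
      return(list(cutoff = gv[[1L]], hit_prob = cum[[1L]]))
    return(list(cutoff = gv[[max(ok)]], hit_prob = cum[[max(ok)]]))
  }
  bgseq <- simulate_background_sequence(bg_model, sim_length, seed)
  sc <- window_scores(pwm, encode_dna(bgseq), bg_model)
  n <- length(sc)
  kmax <- floor(alpha * n)
  sorted <- sort(sc, decreasing = TRUE)
  if (kmax < 1L) return(list(cutoff = sorted[1L] + 1e-9, hit_prob = 0))
  cutoff <- sorted[kmax]
  list(cutoff = cutoff, hit_prob = sum(sc >= cutoff - HIT_TOL) / n)
}

# vectorized weight scores of all windows (one strand)
window_scores <- function(pwm, v, bg_model = NULL) {
  L <- ncol(pwm$matrix)
  n <- length(v)
  if (n < L) return(numeric(0))
  npos <- n - L + 1L
  lp_num <- numeric(npos)
  for (j in seq_len(L))
    lp_num <- lp_num + pwm$logfreq[cbind(v[j:(j + npos - 1L)], j)]
  if (is.null(bg_model) || bg_model$order == 0L) {
    probs <- if (is.null(bg_model)) pwm$background else bg_model$probs
    lp_den <- numeric(npos)
    lb <- log2(probs)
    for (j in seq_len(L))
      lp_den <- lp_den + lb[v[j:(j + npos - 1L)]]
    return(lp_num - lp_den)
  }
  ord <- bg_model$order
  lpb <- log2(bg_model$probs[v])
  lpt <- c(rep(NA_real_, ord), log2(bg_model$trans[cbind(context_index(v, ord),
                                                         v[(ord + 1L):n])]))
  lp_site <- ifelse(is.na(lpt), lpb, lpt)
  # within a window, the first `ord` positions lack full in-window context;
  # use the sequence-wide contextual probability throughout (cheap, exact
  # except at the very start of the sequence)
  csum <- cumsum(c(0, lp_site))
  lp_num - (csum[(L + 1L):(n + 1L)] - csum[seq_len(npos)])
}

#' Scan sequences for PWM hits
#'
#' Both strands of every sequence are scanned; windows with a weight score
#' at or above the per-matrix cutoff are reported. Minus-strand hits are
#' reported by the plus-strand start of the window. Hits are ordered by
#' sequence, position, strand, matrix.
#'
#' @param pwms list of `pwm` objects (or `pfm`s, converted with defaults).
#' @param sequences named character vector of DNA sequences or a FASTA path.
#' @param cutoffs optional named numeric cutoffs per matrix id; missing
#'   cutoffs are calibrated via [calibrate_cutoff()].
#' @param bg_model optional `background_model`.
#' @param alpha type-I rate for cutoff calibration.
#' @param seed seed for empirical calibration.
#' @return data.frame of hits: `seq_id`, `start`, `strand`, `matrix`, `score`.
#' @export
scan_sequences <- function(pwms, sequences, cutoffs = NULL, bg_model = NULL,
                           alpha = 1e-3, seed = 1L) {
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences))
    sequences <- as.character(Biostrings::readDNAStringSet(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  pwms <- lapply(pwms, function(p) if (inherits(p, "pfm")) pfm_to_scoring_pwm(p) else p)
  hits <- list()
  for (pw in pwms) {
    cutoff <- if (!is.null(cutoffs) && pw$id %in% names(cutoffs)) cutoffs[[pw$id]]
    else calibrate_cutoff(pw, bg_model, alpha, seed = seed)$cutoff
    L <- ncol(pw$matrix)
    pw_rc <- pw
    pw_rc$matrix <- pw$matrix[c(4, 3, 2, 1), rev(seq_len(L)), drop = FALSE]
    pw_rc$logfreq <- pw$logfreq[c(4, 3, 2, 1), rev(seq_len(L)), drop = FALSE]
    for (sid in names(sequences)) {
      if (nchar(sequences[[sid]]) < L) next
      v <- encode_dna(sequences[[sid]])
      for (strand in c("+", "-")) {
        sc <- window_scores(if (strand == "+") pw else pw_rc, v, bg_model)
        hit <- which(sc >= cutoff - HIT_TOL)
        if (length(hit))
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = sid, start = hit, strand = strand,
            matrix = pw$id, score = sc[hit])
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(0), start = integer(0), strand = character(0),
               matrix = character(0), score = numeric(0))
  out[order(out$seq_id, out$start, out$strand, out$matrix), , drop = FALSE]
}
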