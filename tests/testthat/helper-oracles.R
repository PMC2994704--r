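# Independent brute-force oracles. These deliberately share no code with
# the package's dynamic programs: probabilities are computed by scoring
# every word of a window, alignments by enumerating every alignment path,
# kernels by materializing the explicit feature map.

AAS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_pfm <- function(L, id = paste0("rp", sample.int(1e9, 1))) {
  m <- matrix(rgamma(4 * L, 1), 4, L)
  pfm(m, id = id)
}

random_aa_str <- function(n) paste(sample(AAS, n, replace = TRUE), collapse = "")

# all words of length U as an integer matrix (4^U rows)
all_words <- function(U) as.matrix(expand.grid(rep(list(1:4), U)))

rc_scores <- function(s) {
  out <- s[4:1, rev(seq_len(ncol(s))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

word_scores <- function(words, scores, first_col) {
  L <- ncol(scores)
  sc <- numeric(nrow(words))
  for (j in seq_len(L))
    sc <- sc + scores[cbind(words[, first_col + j - 1L], j)]
  sc
}

word_probs <- function(words, bg) {
  p <- rep(1, nrow(words))
  for (j in seq_len(ncol(words))) p <- p * bg[words[, j]]
  p
}

# P(score >= threshold) by scoring every word of the motif window
oracle_hit_prob <- function(hm) {
  w <- all_words(ncol(hm$scores))
  sum(word_probs(w, hm$background)[word_scores(w, hm$scores, 1L) >= hm$threshold - 1e-9])
}

# joint hit probability at an offset by scoring every word of the union
# window (B reverse-complemented for the antisense orientation)
oracle_gamma <- function(hmA, hmB, offset, orientation = "sense") {
  sA <- hmA$scores
  sB <- if (orientation == "antisense") rc_scores(hmB$scores) else hmB$scores
  LA <- ncol(sA)
  LB <- ncol(sB)
  u1 <- min(1L, offset + 1L)
  u2 <- max(LA, offset + LB)
  w <- all_words(u2 - u1 + 1L)
  scoreA <- word_scores(w, sA, 1L - u1 + 1L)
  scoreB <- word_scores(w, sB, offset + 1L - u1 + 1L)
  sum(word_probs(w, hmA$background)[scoreA >= hmA$threshold - 1e-9 &
                                      scoreB >= hmB$threshold - 1e-9])
}

# normalized similarity from oracle gammas and oracle hit probabilities
oracle_s_norm <- function(hmA, hmB) {
  pA <- oracle_hit_prob(hmA)
  pB <- oracle_hit_prob(hmB)
  LA <- ncol(hmA$scores)
  LB <- ncol(hmB$scores)
  best <- -Inf
  for (orient in c("sense", "antisense"))
    for (s in (-(LB - 1L)):(LA - 1L))
      best <- max(best, oracle_gamma(hmA, hmB, s, orient) / (pA * pB))
  min(1, 2 * best / (1 / pA + 1 / pB))
}

# exhaustive global alignment enumeration with affine gaps (gap of length
# k costs go + k*ge); returns the optimal score and the sets of identity /
# similarity fractions attained by co-optimal alignments
oracle_nw <- function(seqA, seqB, mat, go, ge, thresholds = numeric(0)) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  n <- length(a)
  m <- length(b)
  results <- list()
  rec <- function(i, j, state, score, matches, len, simc) {
    if (i > n && j > m) {
      results[[length(results) + 1L]] <<-
        list(score = score, identity = matches / len,
             sim = simc / max(1L, len - attr(simc, "gaps")))
      return(invisible())
    }
    if (i <= n && j <= m) {
      s <- mat[a[i], b[j]]
      simc2 <- simc + (s >= thresholds)
      attr(simc2, "gaps") <- attr(simc, "gaps")
      rec(i + 1L, j + 1L, "M", score + s, matches + (a[i] == b[j]), len + 1L, simc2)
    }
    if (i <= n) {
      pen <- if (state == "X") ge else go + ge
      simc2 <- simc
      attr(simc2, "gaps") <- attr(simc, "gaps") + 1L
      rec(i + 1L, j, "X", score - pen, matches, len + 1L, simc2)
    }
    if (j <= m) {
      pen <- if (state == "Y") ge else go + ge
      simc2 <- simc
      attr(simc2, "gaps") <- attr(simc, "gaps") + 1L
      rec(i, j + 1L, "Y", score - pen, matches, len + 1L, simc2)
    }
  }
  simc0 <- rep(0L, length(thresholds))
  attr(simc0, "gaps") <- 0L
  rec(1L, 1L, "S", 0, 0L, 0L, simc0)
  scores <- vapply(results, function(r) r$score, numeric(1))
  best <- max(scores)
  opt <- results[abs(scores - best) < 1e-9]
  list(score = best,
       identities = unique(vapply(opt, function(r) r$identity, numeric(1))),
       sims = if (length(thresholds))
         unique(t(vapply(opt, function(r) r$sim, numeric(length(thresholds)))))
       else NULL)
}

# local alignment maximum score (Gotoh), independent of the package's LAK
oracle_sw <- function(seqA, seqB, mat, go, ge) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  n <- length(a)
  m <- length(b)
  M <- X <- Y <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge, X[i, j + 1L] - ge, 0)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge, Y[i + 1L, j] - ge, 0)
    M[i + 1L, j + 1L] <- mat[a[i], b[j]] +
      max(0, M[i, j], X[i, j], Y[i, j])
    best <- max(best, M[i + 1L, j + 1L])
  }
  best
}

# (k,1)-mismatch kernel through the explicit feature map over all 20^k
# k-mers (k = 3 keeps this at 8000 coordinates)
oracle_mismatch_31 <- function(seqA, seqB) {
  k <- 3L
  gammas <- as.matrix(expand.grid(rep(list(AAS), k), stringsAsFactors = FALSE))
  phi <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    nk <- length(ch) - k + 1L
    counts <- numeric(nrow(gammas))
    for (i in seq_len(nk)) {
      km <- ch[i:(i + k - 1L)]
      d <- rowSums(gammas != matrix(km, nrow(gammas), k, byrow = TRUE))
      counts <- counts + (d <= 1L)
    }
    counts
  }
  pa <- phi(seqA)
  pb <- phi(seqB)
  sum(pa * pb) / sqrt(sum(pa * pa) * sum(pb * pb))
}
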