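# Pairwise sequence comparison primitives for the feature battery.
#
# Global alignments go through Biostrings::pairwiseAlignment; the package
# adopts its affine gap convention throughout: a gap of length k costs
# gap_open + k * gap_extend. The local alignment kernel (LAK), the
# (k,m)-mismatch string kernel and the Chou-Fasman secondary-structure
# predictor are implemented here.

sanitize_aa <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  bad <- !(ch %in% c(AA_ALPHABET20, "X"))
  if (any(bad)) {
    warnf("replacing %d unknown residue(s) by X", sum(bad))
    ch[bad] <- "X"
  }
  paste(ch, collapse = "")
}

#' Global alignment of two sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (gap of length k costs
#' `gap_open + k * gap_extend`). Besides the optimal score, the identity
#' fraction (matching columns / alignment length) and, for each threshold in
#' `sim_thresholds`, the fraction of aligned non-gap columns whose
#' substitution score is at least the threshold are reported.
#'
#' @param seqA,seqB amino-acid strings (unknown residues become `X`).
#' @param matrix substitution matrix (or a name for
#'   [get_substitution_matrix()]).
#' @param gap_open,gap_extend nonnegative gap penalties.
#' @param sim_thresholds numeric vector of similarity thresholds `d`.
#' @return list with `score`, `identity`, `similarity` (named by threshold),
#'   `alignedA`, `alignedB`.
#' @export
global_align <- function(seqA, seqB, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         sim_thresholds = numeric(0)) {
  if (!nzchar(seqA) || !nzchar(seqB)) stopf("sequences must be nonempty")
  if (is.character(matrix)) matrix <- get_substitution_matrix(matrix)
  seqA <- sanitize_aa(seqA)
  seqB <- sanitize_aa(seqB)
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                       substitutionMatrix = matrix,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nongap <- pa != "-" & sa != "-"
  identity <- sum(pa == sa & nongap) / length(pa)
  sim <- vapply(sim_thresholds, function(d) {
    if (!any(nongap)) return(0)
    sc <- matrix[cbind(pa[nongap], sa[nongap])]
    sum(sc >= d) / sum(nongap)
  }, numeric(1))
  names(sim) <- as.character(sim_thresholds)
  list(score = Biostrings::score(aln), identity = identity, similarity = sim,
       alignedA = paste(pa, collapse = ""), alignedB = paste(sa, collapse = ""))
}

# Score-only affine-gap Gotoh DP under the same convention as
# pairwiseAlignment (gap of length k costs go + k*ge); used on the hot
# paths where the aligned strings are not needed.
nw_score <- function(seqA, seqB, matrix, gap_open = 11, gap_extend = 1) {
  chA <- strsplit(sanitize_aa(seqA), "")[[1]]
  chB <- strsplit(sanitize_aa(seqB), "")[[1]]
  n <- length(chA)
  m <- length(chB)
  open <- gap_open + gap_extend
  Mp <- c(0, rep(-Inf, m))                    # previous row of M
  Xp <- rep(-Inf, m + 1L)
  Yp <- c(-Inf, -(gap_open + seq_len(m) * gap_extend))
  for (i in seq_len(n)) {
    srow <- matrix[chA[i], chB]
    Mc <- c(-Inf, srow + pmax(Mp[1:m], Xp[1:m], Yp[1:m]))
    Xc <- pmax(Mp - open, Yp - open, Xp - gap_extend)
    Xc[1L] <- -(gap_open + i * gap_extend)
    Yc <- rep(-Inf, m + 1L)
    for (j in seq_len(m) + 1L)
      Yc[j] <- max(Mc[j - 1L] - open, Xc[j - 1L] - open, Yc[j - 1L] - gap_extend)
    Mp <- Mc; Xp <- Xc; Yp <- Yc
  }
  max(Mp[m + 1L], Xp[m + 1L], Yp[m + 1L])
}

#' Global alignment score normalized to [-1, 1]
#'
#' Applies the self-score normalization `2*s(A,B) / (s(A,A) + s(B,B))`
#' (clipped to `[-1, 1]`) to the Needleman-Wunsch score; the BLOSUM62 form
#' of this score defines the "local TF-pair" gate used for training-pair
#' selection and candidate filtering.
#'
#' @inheritParams global_align
#' @return normalized score in `[-1, 1]`.
#' @export
normalized_align_score <- function(seqA, seqB, matrix = "BLOSUM62",
                                   gap_open = 11, gap_extend = 1) {
  if (is.character(matrix)) matrix <- get_substitution_matrix(matrix)
  s_ab <- nw_score(seqA, seqB, matrix, gap_open, gap_extend)
  s_aa <- self_align_score(seqA, matrix)
  s_bb <- self_align_score(seqB, matrix)
  normalize_feature(s_ab, s_aa, s_bb)
}

self_align_score <- function(seq, matrix) {
  ch <- strsplit(sanitize_aa(seq), "")[[1]]
  sum(matrix[cbind(ch, ch)])  # self-alignment is gapless along the diagonal
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) + exp(b)) elementwise, -Inf-safe
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# raw local alignment kernel, log domain (Saigo et al. 2004 recursion);
# M and X rows are vectorized, the Y/Y2 in-row recurrences are scalar scans
lak_log_kernel <- function(chA, chB, matrix, beta, gap_open, gap_extend) {
  n <- length(chA)
  m <- length(chB)
  gd <- -beta * gap_open
  ge <- -beta * gap_extend
  minf <- rep(-Inf, m + 1L)
  Mp <- minf; Xp <- minf; Yp <- minf; X2p <- minf; Y2p <- minf
  for (i in seq_len(n)) {
    si <- beta * matrix[chA[i], chB]
    prev <- seq_len(m)
    Mc <- c(-Inf, si + lse2(lse2(lse2(rep(0, m), Xp[prev]), Yp[prev]), Mp[prev]))
    Xc <- lse2(gd + Mp, ge + Xp)
    X2c <- lse2(Mp, X2p)
    # Y[j] = LSE_{k<j} (A_k + ge*(j-1-k)) via a stabilized cumulative sum
    A <- lse2(gd + Mc[prev], gd + Xc[prev])
    Yc <- minf
    cA <- max(A)
    if (is.finite(cA)) {
      s <- cumsum(exp(A - cA - ge * prev))
      Yc[prev + 1L] <- cA + ge * prev + log(s)
    }
    B <- lse2(Mc[prev], X2c[prev])
    Y2c <- minf
    cB <- max(B)
    if (is.finite(cB)) {
      s2 <- cumsum(exp(B - cB))
      Y2c[prev + 1L] <- cB + log(s2)
    }
    Mp <- Mc; Xp <- Xc; Yp <- Yc; X2p <- X2c; Y2p <- Y2c
  }
  logsumexp(c(0, X2p[m + 1L], Y2p[m + 1L], Mp[m + 1L]))
}

#' Local alignment kernel (LAK)
#'
#' Log-sum over all local alignments with scores scaled by `beta`, computed
#' in the log domain, and normalized as `K(x,y)/sqrt(K(x,x)*K(y,y))` so that
#' the self-kernel is 1. For large `beta`, `log K / beta` approaches the
#' Smith-Waterman score.
#'
#' @inheritParams global_align
#' @param beta inverse-temperature scaling of alignment scores (> 0).
#' @return normalized kernel value in `(0, 1]`.
#' @export
local_alignment_kernel <- function(seqA, seqB, matrix = "BLOSUM62", beta = 0.5,
                                   gap_open = 11, gap_extend = 1) {
  if (beta <= 0) stopf("beta must be > 0")
  if (is.character(matrix)) matrix <- get_substitution_matrix(matrix)
  chA <- strsplit(sanitize_aa(seqA), "")[[1]]
  chB <- strsplit(sanitize_aa(seqB), "")[[1]]
  kxy <- lak_log_kernel(chA, chB, matrix, beta, gap_open, gap_extend)
  kxx <- lak_log_kernel(chA, chA, matrix, beta, gap_open, gap_extend)
  kyy <- lak_log_kernel(chB, chB, matrix, beta, gap_open, gap_extend)
  exp(kxy - 0.5 * kxx - 0.5 * kyy)
}

# Hamming distances between all k-mers of two character vectors
kmer_hamming <- function(chA, chB, k) {
  na <- length(chA) - k + 1L
  nb <- length(chB) - k + 1L
  D <- matrix(0L, na, nb)
  for (j in seq_len(k)) {
    D <- D + outer(chA[seq_len(na) + j - 1L], chB[seq_len(nb) + j - 1L], "!=")
  }
  D
}

# number of common (k,m)-mismatch neighbors of two k-mers at Hamming
# distance d, alphabet size A (closed forms for m = 0, 1)
mismatch_common_neighbors <- function(d, k, m, A = 20L) {
  if (m == 0L) return(ifelse(d == 0L, 1, 0))
  # m == 1
  ifelse(d == 0L, 1 + k * (A - 1),
         ifelse(d == 1L, A, ifelse(d == 2L, 2, 0)))
}

#' (k,m)-mismatch string kernel
#'
#' Counts, over all pairs of k-mers of the two sequences, the number of
#' common neighbors in the (k,m)-mismatch feature space, normalized so the
#' self-kernel is 1. Supported mismatch budgets: `m = 0` and `m = 1`.
#'
#' @param seqA,seqB amino-acid strings.
#' @param k k-mer length (`k > m`).
#' @param m mismatch budget (0 or 1).
#' @return normalized kernel value in `[0, 1]`.
#' @export
mismatch_kernel <- function(seqA, seqB, k = 3L, m = 1L) {
  if (!(m %in% c(0L, 1L))) stopf("mismatch budget m must be 0 or 1")
  if (k <= m) stopf("require k > m")
  chA <- strsplit(sanitize_aa(seqA), "")[[1]]
  chB <- strsplit(sanitize_aa(seqB), "")[[1]]
  if (length(chA) < k || length(chB) < k) {
    warnf("sequence shorter than k=%d; mismatch kernel set to 0", k)
    return(0)
  }
  raw <- function(a, b) sum(mismatch_common_neighbors(kmer_hamming(a, b, k), k, m))
  kxy <- raw(chA, chB)
  if (kxy == 0) return(0)
  kxy / sqrt(raw(chA, chA) * raw(chB, chB))
}

#' SVM-pairwise profile feature
#'
#' Pearson correlation between the vectors of global-alignment scores of the
#' two sequences against every sequence of a reference panel.
#'
#' @inheritParams global_align
#' @param panel character vector of panel sequences.
#' @return correlation in `[-1, 1]`, or `NA` when either score vector has
#'   zero variance.
#' @export
pairwise_profile_feature <- function(seqA, seqB, panel, matrix = "BLOSUM62",
                                     gap_open = 11, gap_extend = 1) {
  if (length(panel) == 0L) stopf("panel must be nonempty")
  if (is.character(matrix)) matrix <- get_substitution_matrix(matrix)
  va <- vapply(panel, function(p)
    nw_score(seqA, p, matrix, gap_open, gap_extend), numeric(1))
  vb <- vapply(panel, function(p)
    nw_score(seqB, p, matrix, gap_open, gap_extend), numeric(1))
  profile_correlation(va, vb)
}

profile_correlation <- function(va, vb) {
  if (length(va) < 2L || sd(va) == 0 || sd(vb) == 0) {
    warnf("zero-variance profile vector; feature flagged missing")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Predict protein secondary structure (3-state)
#'
#' Deterministic Chou-Fasman-style predictor: per-residue helix, sheet and
#' turn propensities are smoothed with a centered window of width 5 and the
#' arg-max state is assigned (`H` helix, `E` sheet, `C` otherwise).
#'
#' @param sequence amino-acid string.
#' @return string over `{H, E, C}` of the same length.
#' @export
predict_secondary_structure <- function(sequence) {
  ch <- strsplit(sanitize_aa(sequence), "")[[1]]
  if (length(ch) == 0L) stopf("empty sequence")
  prop <- function(scale) {
    v <- unname(scale[ch])
    v[is.na(v)] <- 1  # X: neutral propensity
    v
  }
  smooth5 <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      w <- max(1L, i - 2L):min(n, i + 2L)
      mean(v[w])
    }, numeric(1))
  }
  h <- smooth5(prop(CF_HELIX))
  e <- smooth5(prop(CF_SHEET))
  t <- smooth5(prop(CF_TURN))
  state <- c("H", "E", "C")[max.col(cbind(h, e, t), ties.method = "first")]
  paste(state, collapse = "")
}

#' Align two secondary-structure strings
#'
#' Global alignment of `{H,E,C}` strings under the package's 3x3 structure
#' matrix (match +2, H/E mismatch -2, mismatches against C -1; gaps 4/1).
#'
#' @param ssA,ssB strings over `{H, E, C}`.
#' @param gap_open,gap_extend gap penalties.
#' @return alignment score.
#' @export
align_secondary_structure <- function(ssA, ssB, gap_open = 4, gap_extend = 1) {
  nw_score(ssA, ssB, SS_MATRIX, gap_open, gap_extend)
}
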