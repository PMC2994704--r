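#' @importFrom stats cor sd quantile rbeta runif rnorm setNames aggregate
#' @importFrom utils head tail read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# IUPAC degenerate nucleotide codes -> base sets
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1

check_background <- function(background) {
  if (!is.numeric(background) || length(background) != 4L)
    stopf("background must be a length-4 probability vector")
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6)
    stopf("background must be positive and sum to 1")
  setNames(as.numeric(background) / sum(background), DNA_BASES)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# deterministic sub-seed derivation, kept below 2^31 (chainable)
derive_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483647
  as.integer(h) + 1L
}
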