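# Substitution matrices.
#
# The standard NCBI BLOSUM/PAM series is taken from Biostrings' data sets.
# In addition, the package constructs physicochemical substitution matrices
# from published residue property scales (Chou-Fasman helix/sheet/turn
# propensities, Kyte-Doolittle hydropathy, mean residue volume): two
# residues score high when their property values are close. Any 20x20
# symmetric plain-text matrix can be substituted via
# [load_substitution_matrix()].

# Kyte & Doolittle (1982) hydropathy
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

# Chou & Fasman (1978) conformational propensities
CF_HELIX <- c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11,
              E = 1.51, G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16,
              M = 1.45, F = 1.13, P = 0.57, S = 0.77, T = 0.83, W = 1.08,
              Y = 0.69, V = 1.06)

CF_SHEET <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10,
              E = 0.37, G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74,
              M = 1.05, F = 1.38, P = 0.55, S = 0.75, T = 1.19, W = 1.37,
              Y = 1.47, V = 1.70)

CF_TURN <- c(A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98,
             E = 0.74, G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01,
             M = 0.60, F = 0.60, P = 1.52, S = 1.43, T = 0.96, W = 0.96,
             Y = 1.14, V = 0.50)

# mean residue volume (A^3), Zamyatnin (1972)
AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# property scale -> integer substitution matrix: s(a,b) = round(5 - 10*|za-zb|)
# where z is the scale rescaled to [0,1]; diagonal +5, X column at the floor
property_matrix <- function(scale, name) {
  z <- (scale - min(scale)) / (max(scale) - min(scale))
  m <- round(5 - 10 * abs(outer(z, z, "-")))
  dimnames(m) <- list(names(scale), names(scale))
  m <- add_x_floor(m)
  attr(m, "name") <- name
  m
}

add_x_floor <- function(m) {
  if ("X" %in% rownames(m)) return(m)
  floorv <- min(m)
  m <- rbind(cbind(m, X = floorv), X = c(rep(floorv, ncol(m)), floorv))
  m
}

BIOSTRINGS_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                         "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                         "PAM250")

PROPERTY_MATRICES <- c("CFHELIX", "CFSHEET", "CFTURN", "KDHYDRO", "VOLUME")

# secondary-structure alignment matrix: match +2, H<->E -2, */C mismatch -1
SS_MATRIX <- local({
  m <- matrix(-1, 3, 3, dimnames = list(c("H", "E", "C"), c("H", "E", "C")))
  diag(m) <- 2
  m["H", "E"] <- m["E", "H"] <- -2
  m
})

#' Retrieve a substitution matrix by name
#'
#' Names of the NCBI series (`BLOSUM45/50/62/80/100`, `PAM30/40/70/120/250`)
#' resolve to the tables shipped with Biostrings; `CFHELIX`, `CFSHEET`,
#' `CFTURN`, `KDHYDRO` and `VOLUME` resolve to the package's property-derived
#' physicochemical matrices; anything else is looked up as a file (in
#' `dir` when given) via [load_substitution_matrix()].
#'
#' @param name matrix name or file path.
#' @param dir optional directory searched for matrix files.
#' @return a symmetric numeric matrix with an `X` row/column.
#' @export
get_substitution_matrix <- function(name, dir = NULL) {
  cache <- get_matrix_cache()
  key <- paste0(name, "|", dir %||% "")
  if (!is.null(cache[[key]])) return(cache[[key]])
  m <- if (name %in% BIOSTRINGS_MATRICES) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
  } else if (name %in% PROPERTY_MATRICES) {
    property_matrix(switch(name, CFHELIX = CF_HELIX, CFSHEET = CF_SHEET,
                           CFTURN = CF_TURN, KDHYDRO = KD_HYDROPATHY,
                           VOLUME = AA_VOLUME), name)
  } else {
    path <- if (!is.null(dir) && file.exists(file.path(dir, name)))
      file.path(dir, name) else name
    load_substitution_matrix(path)
  }
  m <- add_x_floor(m)
  cache[[key]] <- m
  m
}

matrix_cache_env <- new.env(parent = emptyenv())
get_matrix_cache <- function() matrix_cache_env

#' Load a substitution matrix from a plain-text file
#'
#' Accepts the EMBOSS-like layout (comment lines starting with `#`, a header
#' row of residue letters, then one row per residue) with either a full
#' square or a lower-triangular body (the triangle is mirrored). The result
#' must be symmetric.
#'
#' @param path text file.
#' @return symmetric numeric matrix.
#' @export
load_substitution_matrix <- function(path) {
  if (!file.exists(path)) stopf("no such matrix file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) < 2L) stopf("%s: truncated matrix file", path)
  header <- strsplit(lines[1], "[ \t]+")[[1]]
  if (!all(nchar(header) == 1L)) stopf("%s: expected single-letter header row", path)
  n <- length(header)
  if (length(lines) != n + 1L)
    stopf("%s: expected %d matrix rows, found %d", path, n, length(lines) - 1L)
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], "[ \t]+")[[1]]
    if (parts[1] != header[i]) stopf("%s: row %d label '%s' != '%s'", path, i, parts[1], header[i])
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) stopf("%s: non-numeric entry in row %d", path, i)
    rows[[i]] <- vals
  }
  triangular <- any(lengths(rows) < n)  # lower-triangular body (mirrored)
  for (i in seq_len(n)) {
    vals <- rows[[i]]
    if (triangular && length(vals) == i) { m[i, 1:i] <- vals; m[1:i, i] <- vals }
    else if (!triangular && length(vals) == n) m[i, ] <- vals
    else stopf("%s: row %d has %d values (expected %d)", path, i, length(vals),
               if (triangular) i else n)
  }
  if (any(is.na(m))) stopf("%s: incomplete matrix", path)
  if (any(abs(m - t(m)) > 1e-9)) stopf("%s: matrix is not symmetric", path)
  m
}
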