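# Motif data types and dialect readers/writers.
#
# The in-memory binding-specificity model is the position frequency matrix
# (PFM): a 4 x L column-stochastic matrix with rows fixed in the order
# A, C, G, T regardless of input dialect.

#' Construct a position frequency matrix (PFM)
#'
#' A PFM stores, for each position of a binding site, the frequency of the
#' four nucleotides. Rows are always A, C, G, T; every column must sum to 1.
#'
#' @param matrix 4 x L numeric matrix of nonnegative values; columns are
#'   normalized to sum to 1 (so raw count matrices are accepted).
#' @param id motif identifier.
#' @param source_count optional number of matrices merged into this one
#'   (used as a weight when merging further).
#' @return an object of class `pfm`.
#' @export
pfm <- function(matrix, id = "pfm", source_count = 1L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stopf("PFM '%s': matrix must have 4 rows (A,C,G,T)", id)
  if (ncol(matrix) < 1L) stopf("PFM '%s': motif length must be >= 1", id)
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stopf("PFM '%s': entries must be finite and nonnegative", id)
  cs <- colSums(matrix)
  if (any(cs <= 0)) stopf("PFM '%s': column %d sums to zero", id, which(cs <= 0)[1])
  matrix <- sweep(matrix, 2L, cs, "/")
  dimnames(matrix) <- list(DNA_BASES, NULL)
  structure(list(id = as.character(id), matrix = matrix,
                 source_count = as.integer(source_count)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s' (length %d, source_count %d)\n",
              x$id, ncol(x$matrix), x$source_count))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Motif length of a PFM
#' @param x a `pfm`.
#' @return integer motif length.
#' @export
pfm_length <- function(x) ncol(x$matrix)

validate_pfm <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "pfm"))
  if (any(abs(colSums(x$matrix) - 1) > tol)) stopf("PFM '%s': columns not stochastic", x$id)
  if (any(x$matrix < 0)) stopf("PFM '%s': negative entries", x$id)
  invisible(TRUE)
}

#' Reverse complement of a PFM
#'
#' Reverses the column order and swaps the A/T and C/G rows, giving the
#' motif read on the opposite strand.
#'
#' @param x a `pfm`.
#' @return the reverse-complemented `pfm`.
#' @export
pfm_revcomp <- function(x) {
  m <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pfm(m, id = paste0(x$id, "_rc"), source_count = x$source_count)
}

#' Convert a count or weight matrix to a PFM
#'
#' Count matrices are normalized by each column's sum. Matrices containing
#' negative entries are interpreted as base-2 log-odds against `background`;
#' they are exponentiated (`background * 2^x`) and then column-normalized.
#'
#' @param x 4 x L numeric matrix (counts, frequencies, or log-odds).
#' @param id motif identifier.
#' @param background length-4 background used only for log-odds input.
#' @return a `pfm`.
#' @export
pwm_to_pfm <- function(x, id = "pfm", background = rep(0.25, 4)) {
  x <- as.matrix(x)
  if (nrow(x) != 4L) stopf("expected a 4-row matrix")
  if (any(x < 0)) {
    background <- check_background(background)
    x <- background * 2^x
  }
  cs <- colSums(x)
  if (any(cs <= 0)) stopf("degenerate column (sum <= 0) at position %d", which(cs <= 0)[1])
  pfm(x, id = id)
}

#' Convert an IUPAC consensus motif to a PFM
#'
#' Each degenerate letter becomes a column giving equal weight to every
#' nucleotide the letter stands for.
#'
#' @param letters IUPAC string (e.g. `"TGASTCA"`).
#' @param id motif identifier.
#' @return a `pfm`.
#' @export
iupac_to_pfm <- function(letters, id = letters) {
  letters <- toupper(letters)
  ch <- strsplit(letters, "")[[1]]
  if (length(ch) == 0L) stopf("empty IUPAC motif")
  bad <- setdiff(ch, names(IUPAC_MAP))
  if (length(bad)) stopf("invalid IUPAC letter(s): %s", paste(unique(bad), collapse = ","))
  m <- vapply(ch, function(l) {
    col <- numeric(4)
    names(col) <- DNA_BASES
    col[IUPAC_MAP[[l]]] <- 1 / length(IUPAC_MAP[[l]])
    col
  }, numeric(4))
  pfm(m, id = id)
}

# Best-effort inverse of iupac_to_pfm; errors when a column is not uniform
# over a base subset (within tol).
pfm_to_iupac <- function(x, tol = 1e-6) {
  vapply(seq_len(ncol(x$matrix)), function(j) {
    col <- x$matrix[, j]
    on <- col > tol
    if (any(abs(col[on] - 1 / sum(on)) > tol))
      stopf("PFM '%s' column %d is not representable as an IUPAC letter", x$id, j)
    for (l in names(IUPAC_MAP))
      if (length(IUPAC_MAP[[l]]) == sum(on) && all(DNA_BASES[on] %in% IUPAC_MAP[[l]]))
        return(l)
    stopf("no IUPAC letter for column %d", j)  # unreachable: all subsets covered
  }, character(1)) |> paste(collapse = "")
}

#' Read motifs from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{jaspar}{`>ID` header, then `A [ n n ... ]` rows for A, C, G, T.}
#'   \item{transfac}{records with an `ID`/`NA` line, a `P0` column header and
#'     numbered rows `01 .. NN` with counts in column order A, C, G, T,
#'     terminated by `XX` or `//`.}
#'   \item{iupac}{one motif per line, `id<TAB>letters`.}
#'   \item{pfm-tsv}{the package's canonical exchange format: `>id` header
#'     line followed by 4 tab-separated rows `A/C/G/T<TAB>values...`.}
#' }
#' Counts are converted to frequencies on reading.
#'
#' @param path input file.
#' @param dialect one of `"jaspar"`, `"transfac"`, `"iupac"`, `"pfm-tsv"`.
#' @return list of `pfm` objects.
#' @export
read_motifs <- function(path, dialect = c("pfm-tsv", "jaspar", "transfac", "iupac")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
         "jaspar"  = parse_jaspar(lines, path),
         "transfac" = parse_transfac(lines, path),
         "iupac"   = parse_iupac(lines, path),
         "pfm-tsv" = parse_pfm_tsv(lines, path))
}

parse_numbers <- function(txt, path, i) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[ \t]+")[[1]]))
  if (length(vals) == 0L || any(is.na(vals)))
    stopf("%s: cannot parse numeric row at line %d", path, i)
  vals
}

parse_jaspar <- function(lines, path) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!startsWith(ln, ">")) stopf("%s: expected '>' header at line %d", path, i)
    id <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]][1]
    rows <- list()
    for (b in DNA_BASES) {
      i <- i + 1L
      if (i > length(lines)) stopf("%s: truncated record '%s'", path, id)
      rl <- trimws(lines[i])
      base <- sub("^([ACGTacgt]).*$", "\\1", rl)
      if (toupper(base) != b) stopf("%s: expected %s row at line %d", path, b, i)
      body <- sub("^[ACGTacgt]", "", rl)
      body <- gsub("[][]", " ", body)
      rows[[b]] <- parse_numbers(body, path, i)
    }
    if (length(unique(lengths(rows))) != 1L)
      stopf("%s: ragged matrix in record '%s'", path, id)
    out[[length(out) + 1L]] <- pfm(do.call(rbind, rows), id = id)
    i <- i + 1L
  }
  out
}

parse_transfac <- function(lines, path) {
  out <- list()
  id <- NULL
  rows <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "XX")) next
    tag <- sub("^([A-Za-z0-9]+).*", "\\1", ln)
    if (tag %in% c("ID", "NA", "AC", "DE")) {
      if (is.null(id) || tag %in% c("ID", "AC"))
        id <- strsplit(ln, "[ \t]+")[[1]][2] %||% id
    } else if (tag == "P0" || tag == "PO") {
      rows <- list()
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(rows)) stopf("%s: matrix row before P0 header at line %d", path, i)
      body <- sub("^[0-9]+", "", ln)
      # trailing consensus letter is allowed and ignored
      body <- sub("[ \t]+[A-Za-z]+$", "", body)
      rows[[length(rows) + 1L]] <- parse_numbers(body, path, i)[1:4]
    } else if (tag == "//") {
      if (!is.null(rows) && length(rows)) {
        out[[length(out) + 1L]] <-
          pfm(t(do.call(rbind, rows)), id = id %||% sprintf("motif%d", length(out) + 1L))
      }
      id <- NULL; rows <- NULL
    }
  }
  if (!is.null(rows) && length(rows))
    out[[length(out) + 1L]] <-
      pfm(t(do.call(rbind, rows)), id = id %||% sprintf("motif%d", length(out) + 1L))
  out
}

parse_iupac <- function(lines, path) {
  lines <- lines[trimws(lines) != ""]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) != 2L) stopf("%s: expected 'id<TAB>letters' at line %d", path, i)
    iupac_to_pfm(parts[2], id = parts[1])
  })
}

parse_pfm_tsv <- function(lines, path) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!startsWith(ln, ">")) stopf("%s: expected '>' header at line %d", path, i)
    hdr <- strsplit(sub("^>", "", ln), "\t")[[1]]
    id <- hdr[1]
    sc <- if (length(hdr) > 1L) as.integer(hdr[2]) else 1L
    rows <- list()
    for (b in DNA_BASES) {
      i <- i + 1L
      if (i > length(lines)) stopf("%s: truncated record '%s'", path, id)
      parts <- strsplit(lines[i], "\t")[[1]]
      if (toupper(parts[1]) != b) stopf("%s: expected %s row at line %d", path, b, i)
      rows[[b]] <- parse_numbers(paste(parts[-1], collapse = " "), path, i)
    }
    if (length(unique(lengths(rows))) != 1L)
      stopf("%s: ragged matrix in record '%s'", path, id)
    out[[length(out) + 1L]] <- pfm(do.call(rbind, rows), id = id, source_count = sc)
    i <- i + 1L
  }
  out
}

#' Write motifs to a file
#'
#' Inverse of [read_motifs()]: `read_motifs(write_motifs(x, f), ...)` returns
#' the same matrices within 1e-9. The `iupac` dialect is only applicable to
#' PFMs whose columns are uniform over a base subset.
#'
#' @param pfms list of `pfm` objects (possibly empty).
#' @param path output file.
#' @param dialect output dialect, see [read_motifs()].
#' @return `path`, invisibly.
#' @export
write_motifs <- function(pfms, path, dialect = c("pfm-tsv", "jaspar", "transfac", "iupac")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) sub("0+$", "", sub("\\.$", "", sprintf("%.10f", v))) # trim trailing zeros
  fmtv <- function(v) vapply(v, function(x) {
    s <- sprintf("%.10f", x); s <- sub("0+$", "", s); sub("\\.$", "", s)
  }, character(1))
  lines <- character(0)
  for (x in pfms) {
    validate_pfm(x)
    lines <- c(lines, switch(dialect,
      "pfm-tsv" = c(sprintf(">%s\t%d", x$id, x$source_count),
                    vapply(DNA_BASES, function(b)
                      paste(c(b, fmtv(x$matrix[b, ])), collapse = "\t"), character(1))),
      "jaspar" = c(paste0(">", x$id),
                   vapply(DNA_BASES, function(b)
                     sprintf("%s [ %s ]", b, paste(fmtv(x$matrix[b, ]), collapse = " ")),
                     character(1))),
      "transfac" = c(paste("ID", x$id), "P0\tA\tC\tG\tT",
                     vapply(seq_len(ncol(x$matrix)), function(j)
                       paste(c(sprintf("%02d", j), fmtv(x$matrix[, j])), collapse = "\t"),
                       character(1)),
                     "XX", "//"),
      "iupac" = paste(x$id, pfm_to_iupac(x), sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}
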