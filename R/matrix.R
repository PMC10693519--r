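# Substitution-matrix handling: NCBI-format parsing and the custom
# normalized scoring matrix with explicit gap scores.

#' The 20 standard amino-acid one-letter codes
#'
#' Ordering follows the NCBI matrix convention (A, R, N, D, ...).
#' @keywords internal
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Gap character used in aligned sequences
#' @keywords internal
GAP_CHAR <- "-"

#' Read a substitution matrix in NCBI format
#'
#' Parses the whitespace-delimited matrix layout distributed with NCBI BLAST
#' (a header row of residue codes followed by one labelled score row per
#' residue; lines starting with `#` are comments). The table is restricted to
#' the 20 standard residues: ambiguity and stop rows/columns (B, Z, X, `*`)
#' present in published files are discarded before anything downstream --
#' in particular before the min/max used for normalization are computed.
#'
#' @param path Path to the matrix file. The package bundles the standard
#'   BLOSUM90 table under `system.file("extdata", "BLOSUM90.txt",
#'   package = "seizurescope")`.
#' @param name Optional name for the matrix; defaults to the file name
#'   without extension.
#' @return An object of class `raw_subst_matrix`: a list with elements
#'   `alphabet` (character vector of 20 residues), `scores` (named 20x20
#'   integer matrix) and `name`.
#' @examples
#' b90 <- read_raw_matrix(system.file("extdata", "BLOSUM90.txt",
#'                                    package = "seizurescope"))
#' b90$scores["W", "W"]  # 11
#' @export
read_raw_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file has no table: ", path)

  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  row_labels <- vapply(body, `[`, character(1L), 1L)
  ncol_expected <- length(header)
  mat <- matrix(NA_real_, nrow = length(body), ncol = ncol_expected,
                dimnames = list(row_labels, header))
  for (i in seq_along(body)) {
    vals <- body[[i]][-1L]
    if (length(vals) != ncol_expected) {
      stop("row '", row_labels[i], "' has ", length(vals),
           " scores, expected ", ncol_expected)
    }
    mat[i, ] <- as.numeric(vals)
  }

  missing <- setdiff(AA_STANDARD, intersect(row_labels, header))
  if (length(missing) > 0L) {
    stop("matrix is missing standard residue row(s): ",
         paste(missing, collapse = ", "))
  }
  mat <- mat[AA_STANDARD, AA_STANDARD, drop = FALSE]

  asym <- which(abs(mat - t(mat)) > 0, arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    i <- asym[1L, 1L]; j <- asym[1L, 2L]
    stop("matrix is not symmetric: score(", AA_STANDARD[i], ",",
         AA_STANDARD[j], ") = ", mat[i, j], " but score(",
         AA_STANDARD[j], ",", AA_STANDARD[i], ") = ", mat[j, i])
  }

  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  structure(list(alphabet = AA_STANDARD, scores = mat, name = name),
            class = "raw_subst_matrix")
}

#' Build the normalized scoring matrix with explicit gap scores
#'
#' Rescales a raw (integer, log-odds) substitution matrix linearly so the
#' 20x20 table spans exactly \[0, 1\], and attaches fixed scores for columns
#' where one sequence has a gap (indel) or both do (dual gap). With the
#' defaults, an insertion or deletion scores -0.5 and a gap aligned to a gap
#' scores 0. Terminal gaps are scored identically to internal gaps.
#'
#' @param raw A `raw_subst_matrix` from [read_raw_matrix()].
#' @param indel_score Score for a gap aligned against a residue (either
#'   direction). Default -0.5.
#' @param dual_gap_score Score for a gap aligned against a gap. Default 0.
#' @return An object of class `scoring_matrix`: list with `alphabet`,
#'   `normalized_scores` (20x20, in \[0,1\]), `indel_score`,
#'   `dual_gap_score`, `source_name`, `normalization_min`,
#'   `normalization_max`.
#' @examples
#' b90 <- read_raw_matrix(system.file("extdata", "BLOSUM90.txt",
#'                                    package = "seizurescope"))
#' sm <- build_scoring_matrix(b90)
#' sm$normalized_scores["W", "W"]  # 1 (the raw maximum)
#' @export
build_scoring_matrix <- function(raw, indel_score = -0.5,
                                 dual_gap_score = 0) {
  stopifnot(inherits(raw, "raw_subst_matrix"))
  lo <- min(raw$scores)
  hi <- max(raw$scores)
  if (hi == lo) stop("constant raw matrix: normalization undefined")
  norm <- (raw$scores - lo) / (hi - lo)
  structure(list(alphabet = raw$alphabet,
                 normalized_scores = norm,
                 indel_score = indel_score,
                 dual_gap_score = dual_gap_score,
                 source_name = raw$name,
                 normalization_min = lo,
                 normalization_max = hi),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("Normalized substitution scoring matrix (", x$source_name, ")\n",
      sep = "")
  cat("  20x20 table rescaled from [", x$normalization_min, ", ",
      x$normalization_max, "] to [0, 1]\n", sep = "")
  cat("  gap vs residue: ", x$indel_score,
      ";  gap vs gap: ", x$dual_gap_score, "\n", sep = "")
  invisible(x)
}

#' Path to the bundled BLOSUM90 fixture
#' @return File path of the NCBI-format BLOSUM90 table shipped with the
#'   package.
#' @export
blosum90_path <- function() {
  system.file("extdata", "BLOSUM90.txt", package = "seizurescope",
              mustWork = TRUE)
}
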