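# Bundled data assets: the 16 PB reference dihedral vectors and the PB
# substitution matrix used for SVR realignment.

PB_LETTERS <- letters[1:16]
PB_UNASSIGNED <- "Z"

#' Protein Block reference dihedral vectors
#'
#' Loads the 16 reference vectors of the PB structural alphabet.  Each block
#' letter (a..p) is defined by eight backbone torsion angles over five
#' consecutive residues, ordered psi(i-2), phi(i-1), psi(i-1), phi(i),
#' psi(i), phi(i+1), psi(i+1), phi(i+2), in degrees.  The default table is a
#' transcription of the published PB definitions bundled with the package;
#' supply `path` to use a different table with the same TSV layout
#' (header line, then 16 rows: letter + 8 angles).
#'
#' @param path optional TSV path overriding the bundled table.
#' @return A 16 x 8 numeric matrix with rownames a..p, class
#'   `pb_definitions`.
#' @export
pb_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pb_definitions.tsv",
                                package = "pbsvr", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 16L || ncol(tab) != 9L)
    stop_pbsvr("pbsvr_bad_asset", "PB definitions must have 16 rows x 9 columns")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  if (!identical(sort(rownames(m)), PB_LETTERS))
    stop_pbsvr("pbsvr_bad_asset", "PB definitions must cover letters a..p")
  m <- m[PB_LETTERS, , drop = FALSE]
  if (any(m <= -180 | m > 180))
    stop_pbsvr("pbsvr_bad_asset", "PB reference angles must lie in (-180, 180]")
  structure(m, class = c("pb_definitions", "matrix"))
}

#' Protein Block substitution matrix
#'
#' Loads a symmetric 16 x 16 PB substitution matrix (rows/columns a..p) for
#' scoring PB alignments.  The bundled default is a synthetic matrix derived
#' from the angular dissimilarity (rmsda) between the PB reference vectors,
#' `M(x, y) = (45 - rmsda(ref_x, ref_y)) / 22.5` (diagonal = 2); see the
#' package vignette for the rationale and its relation to the -0.42
#' classification cutoff.  Supply `path` to use a different matrix (17-line
#' TSV: header, then 16 rows letter + 16 values).
#'
#' @param path optional TSV path overriding the bundled matrix.
#' @return A 16 x 16 symmetric numeric matrix, class `pb_substitution_matrix`.
#' @export
pb_substitution_matrix <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pb_substitution_matrix_synthetic.tsv",
                                package = "pbsvr", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  colnames(m) <- sub("^X?", "", colnames(m))
  if (!identical(sort(rownames(m)), PB_LETTERS) ||
      !identical(sort(colnames(m)), PB_LETTERS))
    stop_pbsvr("pbsvr_bad_asset", "substitution matrix must be 16 x 16 over a..p")
  m <- m[PB_LETTERS, PB_LETTERS]
  if (max(abs(m - t(m))) > 1e-9)
    stop_pbsvr("pbsvr_bad_asset", "substitution matrix must be symmetric")
  if (any(diag(m) < apply(m, 1, max)))
    stop_pbsvr("pbsvr_bad_asset", "diagonal must be each row's maximum")
  structure(m, class = c("pb_substitution_matrix", "matrix"))
}
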