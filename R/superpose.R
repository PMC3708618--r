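# Rigid-body least-squares superposition, per-column CA distances, RMSD and
# the length-aware structural distance metric (SDM).

#' Least-squares rigid-body superposition
#'
#' Finds the proper rotation R (det = +1, no reflection) and translation t
#' minimizing the sum of squared distances between `coordsA` and
#' `coordsB %*% R + t`, via the closed-form SVD solution of the orthogonal
#' Procrustes problem.
#'
#' @param coordsA,coordsB n x 3 matrices of paired CA coordinates (n >= 3,
#'   not all collinear).
#' @return A list with `transform` (class `rigid_transform`: `rotation`
#'   3 x 3, `translation` 3-vector) and `rmsd` (Angstrom, the minimized
#'   value).
#' @export
fit_superposition <- function(coordsA, coordsB) {
  A <- matrix(as.numeric(coordsA), ncol = 3)
  B <- matrix(as.numeric(coordsB), ncol = 3)
  n <- nrow(A)
  if (nrow(B) != n)
    stop_pbsvr("pbsvr_length_mismatch", "coordinate lists differ in length")
  if (n < 3L)
    stop_pbsvr("pbsvr_degenerate_geometry", "need at least 3 point pairs")
  muA <- colMeans(A); muB <- colMeans(B)
  Ac <- sweep(A, 2, muA); Bc <- sweep(B, 2, muB)
  if (svd(Ac)$d[2] < 1e-8 || svd(Bc)$d[2] < 1e-8)
    stop_pbsvr("pbsvr_degenerate_geometry",
               "points are collinear: rotation is not determined")
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- as.numeric(muA - muB %*% R)
  tf <- structure(list(rotation = R, translation = t),
                  class = "rigid_transform")
  resid <- Bc %*% R - Ac
  list(transform = tf, rmsd = sqrt(mean(rowSums(resid^2))))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(sprintf("%.6f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' RMSD in a fixed frame (no refitting)
#'
#' Root mean square CA-CA Euclidean distance between paired coordinates as
#' given, without superposition.  Used for "before" values in an existing
#' global frame.
#'
#' @param coordsA,coordsB equal-length n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed_frame <- function(coordsA, coordsB) {
  A <- matrix(as.numeric(coordsA), ncol = 3)
  B <- matrix(as.numeric(coordsB), ncol = 3)
  if (nrow(A) != nrow(B) || nrow(A) == 0L)
    stop_pbsvr("pbsvr_length_mismatch", "coordinate lists differ in length")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-column CA-CA distances under a superposition
#'
#' For each alignment column pairing residues in both chains, the Euclidean
#' CA-CA distance after applying `transform` to chain B; NA at gap columns.
#'
#' @param aln a [pairwise_alignment()].
#' @param chainA,chainB [backbone_chain()] objects.
#' @param transform `rigid_transform` applied to chain B.
#' @return Numeric vector, one value (or NA) per alignment column.
#' @export
column_distances <- function(aln, chainA, chainB, transform) {
  caB <- apply_transform(chainB$CA, transform)
  ncol <- nchar(aln$rowA)
  out <- rep(NA_real_, ncol)
  both <- !is.na(aln$colmapA) & !is.na(aln$colmapB)
  ia <- aln$colmapA[both]; ib <- aln$colmapB[both]
  if (any(ia > length(chainA)) || any(ib > length(chainB)))
    stop_pbsvr("pbsvr_bad_colmap", "column map exceeds chain length")
  out[both] <- sqrt(rowSums((chainA$CA[ia, , drop = FALSE] -
                               caB[ib, , drop = FALSE])^2))
  out
}

#' Structural distance metric (SDM)
#'
#' A length-aware dissimilarity derived from RMSD: identical, fully
#' equivalenced fragments score 0 and the score grows with RMSD at fixed
#' length and with the unequivalenced fraction.  The default functional form
#' is
#' \deqn{SDM = -100 \ln( w_1 N_{eq}/\max(L_A, L_B) + w_2 / (1 + RMSD/d_0) )}
#' with \eqn{w_1 = w_2 = 0.5} and \eqn{d_0 = 3} Angstrom.  The metric is a
#' plug-in: pipeline functions accept any function with this signature.
#'
#' @param rmsd RMSD of the equivalenced CA pairs (Angstrom).
#' @param n_equiv number of equivalenced residue pairs (>= 1).
#' @param lenA,lenB fragment lengths (residues).
#' @param w1,w2 mixture weights (sum to 1).
#' @param d0 RMSD softening scale in Angstrom.
#' @return Non-negative score.
#' @export
sdm <- function(rmsd, n_equiv, lenA, lenB, w1 = 0.5, w2 = 0.5, d0 = 3) {
  if (n_equiv < 1L)
    stop_pbsvr("pbsvr_empty_equivalence", "SDM needs at least one equivalenced pair")
  s_len <- n_equiv / max(lenA, lenB)
  s_rmsd <- 1 / (1 + rmsd / d0)
  -100 * log(w1 * s_len + w2 * s_rmsd)
}
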