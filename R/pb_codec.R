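# Backbone dihedrals and Protein Block encoding.

#' Torsion angle of four points
#'
#' IUPAC convention: 0 degrees for cis (eclipsed), 180 for trans, sign by the
#' right-hand rule looking down the p2 -> p3 bond; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    stop_pbsvr("pbsvr_degenerate_geometry", "coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop_pbsvr("pbsvr_degenerate_geometry",
               "collinear points: dihedral undefined")
  u2 <- unit3(b2)
  ang <- atan2(sum(cross3(n1, u2) * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Backbone phi/psi dihedral series
#'
#' Computes per-residue phi (C(i-1), N(i), CA(i), C(i)) and psi (N(i), CA(i),
#' C(i), N(i+1)) angles.  phi is undefined (NA) at the first residue, psi at
#' the last.  Where consecutive CA atoms are further apart than
#' `break_threshold` the chain is treated as broken and the dihedrals
#' spanning the break (psi(i) and phi(i+1)) are undefined.
#'
#' @param chain a [backbone_chain()] of length >= 2.
#' @param break_threshold CA-CA distance (Angstrom) above which a chain break
#'   is declared; default 4.5 (generously above the ~3.8 trans and ~2.9 cis
#'   peptide separations).
#' @return A data.frame with columns `phi`, `psi` (degrees, NA where
#'   undefined), one row per residue.
#' @export
compute_dihedrals <- function(chain, break_threshold = 4.5) {
  n <- length(chain)
  if (n < 2L) stop_pbsvr("pbsvr_short_chain", "need at least 2 residues")
  phi <- psi <- rep(NA_real_, n)
  ca <- chain$CA
  gap <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  broken <- gap > break_threshold  # break between i and i+1
  dih <- function(a, b, c, d) {
    tryCatch(dihedral_angle(a, b, c, d), error = function(e) NA_real_)
  }
  for (i in seq_len(n)) {
    if (i > 1L && !broken[i - 1L])
      phi[i] <- dih(chain$C[i - 1L, ], chain$N[i, ], chain$CA[i, ], chain$C[i, ])
    if (i < n && !broken[i])
      psi[i] <- dih(chain$N[i, ], chain$CA[i, ], chain$C[i, ], chain$N[i + 1L, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' Angular dissimilarity between an 8-angle window and a PB reference
#'
#' Root mean square of wrapped angular differences (each in \[0, 180\])
#' over the 8 positions.
#'
#' @param window,reference numeric 8-vectors of angles in degrees.
#' @return Non-negative dissimilarity in degrees.
#' @export
rmsda <- function(window, reference) {
  if (length(window) != 8L || length(reference) != 8L)
    stop_pbsvr("pbsvr_bad_window", "rmsda needs two 8-angle vectors")
  if (anyNA(window) || anyNA(reference))
    stop_pbsvr("pbsvr_undefined_angle", "undefined angle in rmsda input")
  sqrt(mean(angle_diff(window, reference)^2))
}

# the 8-angle window at position i: psi(i-2), phi(i-1), psi(i-1), phi(i),
# psi(i), phi(i+1), psi(i+1), phi(i+2); NA if out of range
pb_window <- function(dihedrals, i) {
  n <- nrow(dihedrals)
  if (i < 3L || i > n - 2L) return(rep(NA_real_, 8L))
  c(dihedrals$psi[i - 2L], dihedrals$phi[i - 1L], dihedrals$psi[i - 1L],
    dihedrals$phi[i], dihedrals$psi[i],
    dihedrals$phi[i + 1L], dihedrals$psi[i + 1L], dihedrals$phi[i + 2L])
}

#' Encode a dihedral series as a Protein Block sequence
#'
#' For each position with a complete 8-angle window the PB letter minimizing
#' [rmsda()] against the 16 reference vectors is assigned (ties broken
#' alphabetically); positions without a complete window -- always including
#' the two first and two last residues -- receive the unassigned sentinel
#' "Z".
#'
#' @param dihedrals data.frame from [compute_dihedrals()].
#' @param defs PB reference vectors from [pb_definitions()].
#' @return Character vector of per-residue symbols over a..p and "Z".
#' @export
assign_pbs <- function(dihedrals, defs = pb_definitions()) {
  n <- nrow(dihedrals)
  out <- rep(PB_UNASSIGNED, n)
  if (n < 5L) return(out)
  for (i in 3:(n - 2L)) {
    w <- pb_window(dihedrals, i)
    if (anyNA(w)) next
    d <- vapply(seq_len(16L), function(k) rmsda(w, defs[k, ]), numeric(1))
    out[i] <- PB_LETTERS[which.min(d)]  # which.min: first minimum = alphabetical
  }
  out
}

#' Encode a backbone chain as a Protein Block sequence
#'
#' Convenience wrapper: [compute_dihedrals()] then [assign_pbs()].
#'
#' @inheritParams compute_dihedrals
#' @inheritParams assign_pbs
#' @return Character vector of per-residue PB symbols.
#' @export
encode_pbs <- function(chain, defs = pb_definitions(), break_threshold = 4.5) {
  assign_pbs(compute_dihedrals(chain, break_threshold), defs)
}
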