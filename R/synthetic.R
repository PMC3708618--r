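# Synthetic backbone generator: internal-coordinate chain building and
# homolog pairs with known ground truth.

#' Standard backbone covalent geometry
#'
#' Canonical trans-peptide values: bond lengths N-CA 1.458, CA-C 1.525,
#' C-N 1.329 Angstrom; bond angles C-N-CA 121.7, N-CA-C 111.2,
#' CA-C-N 116.2 degrees; omega 180.
#'
#' @param n_ca,ca_c,c_n bond lengths in Angstrom.
#' @param ang_n,ang_ca,ang_c bond angles in degrees.
#' @param omega peptide torsion in degrees.
#' @return A `backbone_geometry` list.
#' @export
backbone_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                              ang_n = 121.7, ang_ca = 111.2, ang_c = 116.2,
                              omega = 180) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n,
            ang_n = ang_n, ang_ca = ang_ca, ang_c = ang_c, omega = omega)
  if (any(unlist(g[1:3]) <= 1.0) || any(unlist(g[1:3]) >= 2.0))
    stop_pbsvr("pbsvr_bad_geometry", "bond lengths must lie in (1, 2) Angstrom")
  if (any(unlist(g[4:6]) <= 90) || any(unlist(g[4:6]) >= 150))
    stop_pbsvr("pbsvr_bad_geometry", "bond angles must lie in (90, 150) degrees")
  structure(g, class = "backbone_geometry")
}

# NeRF atom placement: position a new atom at bond length r from c, bond
# angle theta (b..c..new at c) and torsion tau (a-b-c-new) about b->c.
place_atom <- function(a, b, c, r, theta, tau) {
  th <- theta * pi / 180; tr <- tau * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(tr), -r * sin(th) * sin(tr))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a backbone chain from a phi/psi script
#'
#' Constructs an N/CA/C backbone by sequential internal-coordinate placement
#' with fixed covalent geometry and trans peptide bonds.  Recomputing
#' dihedrals on the result recovers the script exactly (phi at residues
#' 2..n, psi at 1..n-1); phi\[1\] and psi\[n\] are unused.
#'
#' @param phi,psi numeric vectors of equal length (>= 2), degrees.
#' @param geometry a [backbone_geometry()].
#' @param chain_id chain identifier for the result.
#' @param aa one-letter codes, recycled (default poly-alanine).
#' @return A [backbone_chain()].
#' @export
build_backbone <- function(phi, psi, geometry = backbone_geometry(),
                           chain_id = "A", aa = "A") {
  n <- length(phi)
  if (length(psi) != n || n < 2L)
    stop_pbsvr("pbsvr_bad_script", "phi/psi must have equal length >= 2")
  g <- geometry
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  angc <- g$ang_ca * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(angc), sin(angc), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$c_n, g$ang_c, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$n_ca, g$ang_n, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$ca_c, g$ang_ca, phi[i])
  }
  backbone_chain(chain_id, seq_len(n), rep("", n),
                 rep_len(strsplit(aa, "")[[1]], n), N, CA, C)
}

#' Recipe for a synthetic homolog pair
#'
#' Describes a base phi/psi script plus a list of edits applied to produce
#' the homolog.  Supported edit kinds: `rigid_rotate_loop` (rotate the span
#' rigidly about the axis through its two flanking CA atoms -- internal
#' dihedrals preserved, orientation changed), `change_dihedrals` (rebuild
#' the span with new, distant phi/psi bridged back onto the flank),
#' `insert`/`delete` (rebuild the span with more/fewer residues), and
#' `substitute_aa` (amino-acid relabelling only).
#'
#' @param phi,psi base script (degrees).
#' @param edits list of edits, each `list(kind=, start=, end=, ...)` with
#'   1-based residue spans; edits must not overlap and must leave at least
#'   one unedited residue on each side.
#' @return A `pair_recipe` list.
#' @export
pair_recipe <- function(phi, psi, edits = list()) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  spans <- unlist(lapply(edits, function(e) e$start:e$end))
  if (anyDuplicated(spans))
    stop_pbsvr("pbsvr_bad_recipe", "edit spans overlap")
  for (e in edits)
    if (e$start < 2L || e$end > n - 1L || e$start > e$end)
      stop_pbsvr("pbsvr_bad_recipe", "edit span out of range")
  structure(list(phi = phi, psi = psi, edits = edits, n = n),
            class = "pair_recipe")
}

#' Convenience recipe: strand-loop-strand with one edit
#'
#' Builds a base script of extended-strand flanks around a helical loop
#' (which bulges away from the flank axis, so a rigid rotation displaces it
#' well beyond 3 Angstrom) and applies one edit of the requested kind to
#' the loop span.
#'
#' @param kind edit kind ("none" for an identical pair); see [pair_recipe()].
#' @param flank residues per flank (default 14).
#' @param loop loop length in residues (default 9).
#' @param angle rotation angle in degrees for `rigid_rotate_loop`
#'   (default 140).
#' @param k residues inserted/deleted for `insert`/`delete` (default 2).
#' @return A `pair_recipe`.
#' @export
loop_recipe <- function(kind = c("none", "rigid_rotate_loop",
                                 "change_dihedrals", "insert", "delete",
                                 "substitute_aa"),
                        flank = 14L, loop = 9L, angle = 140, k = 2L) {
  kind <- match.arg(kind)
  phi <- c(rep(-120, flank), rep(-65, loop), rep(-120, flank))
  psi <- c(rep(130, flank), rep(-38, loop), rep(130, flank))
  edits <- if (kind == "none") list() else
    list(list(kind = kind, start = flank + 1L, end = flank + loop,
              angle = angle, k = k))
  pair_recipe(phi, psi, edits)
}

# rotate points about the axis through p0 with unit direction u by ang deg
rotate_about_axis <- function(pts, p0, u, ang) {
  th <- ang * pi / 180
  u <- unit3(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(pts, 2, p0) %*% t(R), 2, p0, `+`)
}

# build a fragment of m residues continuing from chain residue (start-1)
# with a given phi/psi script; psi of the anchor residue is preserved
grow_fragment <- function(chain, start, phi, psi, geometry) {
  g <- geometry
  m <- length(phi)
  N <- CA <- C <- matrix(NA_real_, m, 3)
  prevN <- chain$N[start - 1L, ]; prevCA <- chain$CA[start - 1L, ]
  prevC <- chain$C[start - 1L, ]
  psi_anchor <- dihedral_angle(prevN, prevCA, prevC, chain$N[start, ])
  psis <- c(psi_anchor, psi)
  for (i in seq_len(m)) {
    N[i, ] <- place_atom(prevN, prevCA, prevC, g$c_n, g$ang_c, psis[i])
    CA[i, ] <- place_atom(prevCA, prevC, N[i, ], g$n_ca, g$ang_n, g$omega)
    C[i, ] <- place_atom(prevC, N[i, ], CA[i, ], g$ca_c, g$ang_ca, phi[i])
    prevN <- N[i, ]; prevCA <- CA[i, ]; prevC <- C[i, ]
  }
  list(N = N, CA = CA, C = C)
}

# draw a replacement fragment of len_new residues whose dihedrals are far
# from the base script and which lands close enough to the downstream
# anchor (CA-CA jump <= 4.2 A) to keep the chain intact; rejection sampled,
# keeping the best try
sample_bridging_fragment <- function(chain, s, t, len_new, recipe, geometry) {
  phi0 <- mean(recipe$phi[s:t]); psi0 <- mean(recipe$psi[s:t])
  anchorCA <- chain$CA[t + 1L, ]
  best <- NULL; best_gap <- Inf
  for (try in seq_len(400L)) {
    dphi <- stats::runif(len_new, 90, 270) * sample(c(-1, 1), len_new, TRUE)
    dpsi <- stats::runif(len_new, 90, 270) * sample(c(-1, 1), len_new, TRUE)
    frag <- grow_fragment(chain, s, wrap_angle(phi0 + dphi),
                          wrap_angle(psi0 + dpsi), geometry)
    gap <- sqrt(sum((frag$CA[len_new, ] - anchorCA)^2))
    if (gap < best_gap) { best <- frag; best_gap <- gap }
    if (gap <= 4.2) break
  }
  best
}

#' Generate a synthetic homolog pair with ground truth
#'
#' Builds chain A from the recipe's base script and chain B by applying the
#' edits, together with the induced pairwise alignment and a ground-truth
#' record per edit (intended span in alignment columns, expected similarity
#' class, achieved CA displacement).  Deterministic for a fixed seed.
#'
#' @param recipe a [pair_recipe()].
#' @param seed integer RNG seed (consumed by the fragment resampling of
#'   `change_dihedrals`, `insert` and `delete` edits).
#' @param geometry a [backbone_geometry()].
#' @return List with `chainA`, `chainB`, `alignment`
#'   ([pairwise_alignment()]) and `truth` (list of per-edit records with
#'   `kind`, `start`, `end` residue span, `span_cols` alignment-column
#'   range, `expected_class`, and `max_displacement` where applicable).
#' @export
make_homolog_pair <- function(recipe, seed = 1L,
                              geometry = backbone_geometry()) {
  with_seed(seed, {
    chainA <- build_backbone(recipe$phi, recipe$psi, geometry, chain_id = "A")
    n <- recipe$n
    # chainB0: same indexing as A, with in-place (length-preserving) edits
    chainB0 <- chainA
    chainB0$chain_id <- "B"
    edits <- recipe$edits[order(vapply(recipe$edits, `[[`, 1L, "start"))]
    for (e in edits) {
      if (e$kind == "rigid_rotate_loop") {
        idx <- e$start:e$end
        p0 <- chainB0$CA[e$start - 1L, ]
        u <- chainB0$CA[e$end + 1L, ] - p0
        for (atom in c("N", "CA", "C"))
          chainB0[[atom]][idx, ] <- rotate_about_axis(
            chainB0[[atom]][idx, , drop = FALSE], p0, u, e$angle %||% 140)
      } else if (e$kind == "substitute_aa") {
        chainB0$aa[e$start:e$end] <-
          rep_len(strsplit(e$aa %||% "G", "")[[1]], e$end - e$start + 1L)
      }
    }
    # replacement fragments for conformation/length edits (ascending order)
    frags <- vector("list", length(edits))
    for (k in seq_along(edits)) {
      e <- edits[[k]]
      if (!e$kind %in% c("change_dihedrals", "insert", "delete")) next
      la <- e$end - e$start + 1L
      len_new <- switch(e$kind, change_dihedrals = la,
                        insert = la + (e$k %||% 2L),
                        delete = la - (e$k %||% 2L))
      if (len_new < 1L)
        stop_pbsvr("pbsvr_bad_recipe", "delete removes the whole span")
      frags[[k]] <- sample_bridging_fragment(chainB0, e$start, e$end,
                                             len_new, recipe, geometry)
    }

    # assemble chain B and the column maps segment by segment
    Bn <- Bca <- Bc <- matrix(numeric(0), 0, 3)
    Baa <- character(0)
    ia <- ib <- integer(0)   # per column: residue index or NA
    truth <- list()
    pos <- 1L                # next A residue to emit
    bcount <- 0L
    emit_plain <- function(rng) {
      Bn <<- rbind(Bn, chainB0$N[rng, , drop = FALSE])
      Bca <<- rbind(Bca, chainB0$CA[rng, , drop = FALSE])
      Bc <<- rbind(Bc, chainB0$C[rng, , drop = FALSE])
      Baa <<- c(Baa, chainB0$aa[rng])
      ia <<- c(ia, rng)
      ib <<- c(ib, bcount + seq_along(rng))
      bcount <<- bcount + length(rng)
    }
    for (k in seq_along(edits)) {
      e <- edits[[k]]
      if (e$start > pos) emit_plain(pos:(e$start - 1L))
      la <- e$end - e$start + 1L
      col0 <- length(ia)
      if (is.null(frags[[k]])) {        # in-place edit: 1:1 columns
        emit_plain(e$start:e$end)
      } else {
        frag <- frags[[k]]
        lb <- nrow(frag$CA)
        w <- max(la, lb)
        Bn <- rbind(Bn, frag$N); Bca <- rbind(Bca, frag$CA)
        Bc <- rbind(Bc, frag$C); Baa <- c(Baa, rep("A", lb))
        ia <- c(ia, e$start:e$end, rep(NA_integer_, w - la))
        ib <- c(ib, bcount + seq_len(lb), rep(NA_integer_, w - lb))
        bcount <- bcount + lb
      }
      rec <- list(kind = e$kind, start = e$start, end = e$end,
                  span_cols = c(col0 + 1L, length(ia)),
                  expected_class = switch(e$kind,
                                          rigid_rotate_loop = "similar",
                                          change_dihedrals = "dissimilar",
                                          insert = "svr_only",
                                          delete = "svr_only",
                                          substitute_aa = "none"))
      if (e$kind %in% c("rigid_rotate_loop", "change_dihedrals")) {
        idxA <- e$start:e$end
        nb <- min(la, if (is.null(frags[[k]])) la else nrow(frags[[k]]$CA))
        bi <- utils::tail(seq_len(bcount), if (is.null(frags[[k]])) la
                          else nrow(frags[[k]]$CA))[seq_len(nb)]
        disp <- sqrt(rowSums((chainA$CA[idxA[seq_len(nb)], , drop = FALSE] -
                                Bca[bi, , drop = FALSE])^2))
        rec$max_displacement <- max(disp)
        if (max(disp) <= 3)
          warning("edit displacement <= 3 Angstrom; span may not segment as SVR",
                  call. = FALSE)
      }
      truth[[length(truth) + 1L]] <- rec
      pos <- e$end + 1L
    }
    if (pos <= n) emit_plain(pos:n)

    chainB <- backbone_chain("B", seq_len(bcount), rep("", bcount), Baa,
                             Bn, Bca, Bc)
    rowA <- ifelse(is.na(ia), "-", chainA$aa[pmax(ia, 1L)])
    rowB <- ifelse(is.na(ib), "-", Baa[pmax(ib, 1L)])
    aln <- pairwise_alignment(paste(rowA, collapse = ""),
                              paste(rowB, collapse = ""))
    list(chainA = chainA, chainB = chainB, alignment = aln, truth = truth)
  })
}

#' Write a synthetic pair to disk
#'
#' Writes the two chains as PDB files, the induced alignment as aligned
#' FASTA and the ground truth as a TSV.
#'
#' @param pair result of [make_homolog_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_pair <- function(pair, dir, prefix = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pA <- file.path(dir, paste0(prefix, "_A.pdb"))
  pB <- file.path(dir, paste0(prefix, "_B.pdb"))
  pF <- file.path(dir, paste0(prefix, ".afa"))
  pT <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_chain_pdb(pair$chainA, pA)
  write_chain_pdb(pair$chainB, pB)
  writeLines(c(">chainA", pair$alignment$rowA, ">chainB",
               pair$alignment$rowB), pF)
  tr <- do.call(rbind, lapply(pair$truth, function(r)
    data.frame(kind = r$kind, start = r$start, end = r$end,
               col_start = r$span_cols[1], col_end = r$span_cols[2],
               expected_class = r$expected_class,
               max_displacement = r$max_displacement %||% NA_real_)))
  if (is.null(tr)) tr <- data.frame(kind = character(0))
  write.table(tr, pT, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(chainA = pA, chainB = pB, alignment = pF, truth = pT))
}

# single-chain PDB writer (N/CA/C records)
write_chain_pdb <- function(chain, path) {
  n <- length(chain)
  ety <- rep(c("N", "CA", "C"), n)
  idx <- rep(seq_len(n), each = 3)
  xyz <- matrix(NA_real_, 3 * n, 3)
  xyz[ety == "N", ] <- chain$N
  xyz[ety == "CA", ] <- chain$CA
  xyz[ety == "C", ] <- chain$C
  bio3d::write.pdb(file = path, xyz = as.numeric(t(round(xyz, 3))),
                   type = rep("ATOM", 3 * n), resno = chain$resno[idx],
                   resid = bio3d::aa123(chain$aa[idx]),
                   eleno = seq_len(3 * n), elety = ety,
                   chain = rep(chain$chain_id, 3 * n),
                   insert = chain$ins[idx])
  invisible(path)
}
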