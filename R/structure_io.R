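# Structure input/output: backbone extraction from PDB/mmCIF and writing of
# superposed coordinate files.

#' Backbone chain objects
#'
#' A `backbone_chain` holds one protein chain's backbone: author residue
#' numbering (with insertion codes), one-letter amino-acid codes and the
#' N, CA and C coordinates (Angstrom) as n x 3 matrices.  Residue order
#' follows file order; every residue carries all three backbone atoms.
#'
#' @param chain_id single character chain identifier.
#' @param resno integer author residue numbers.
#' @param ins insertion codes ("" where absent).
#' @param aa one-letter amino-acid codes.
#' @param N,CA,C n x 3 coordinate matrices in Angstrom.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(chain_id, resno, ins, aa, N, CA, C) {
  n <- length(resno)
  N <- matrix(as.numeric(N), ncol = 3)
  CA <- matrix(as.numeric(CA), ncol = 3)
  C <- matrix(as.numeric(C), ncol = 3)
  stopifnot(n >= 1, length(aa) == n, length(ins) == n,
            nrow(N) == n, nrow(CA) == n, nrow(C) == n)
  structure(
    list(chain_id = as.character(chain_id), resno = as.integer(resno),
         ins = as.character(ins), aa = as.character(aa),
         N = N, CA = CA, C = C),
    class = "backbone_chain"
  )
}

#' @export
length.backbone_chain <- function(x) length(x$resno)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> chain %s, %d residues (%s...)\n",
              x$chain_id, length(x), substr(chain_sequence(x), 1, 20)))
  invisible(x)
}

#' One-letter sequence of a backbone chain
#'
#' @param chain a [backbone_chain()].
#' @return A single string of one-letter codes.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")

#' Read one chain's backbone from a structure file
#'
#' Parses a PDB or mmCIF file (chosen by extension: `.cif`/`.mmcif` are read
#' as mmCIF, anything else as PDB) and extracts the N/CA/C backbone of one
#' chain.  HETATM records are excluded; alternate locations are resolved to
#' the highest occupancy (ties to the first in file order); residues missing
#' any of the three backbone atoms are dropped with a warning.
#'
#' @param path structure file path.
#' @param chain_id chain identifier to extract.
#' @param model_index 1-based model number (multi-model/NMR files); only the
#'   selected model is read.
#' @return A [backbone_chain()].
#' @export
read_backbone <- function(path, chain_id, model_index = 1L) {
  if (!file.exists(path))
    stop_pbsvr("pbsvr_missing_file", sprintf("structure file not found: %s", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)

  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop_pbsvr("pbsvr_bad_model", sprintf("model %d not present", model_index))
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  if (!chain_id %in% unique(at$chain))
    stop_pbsvr("pbsvr_unknown_chain",
               sprintf("chain '%s' not found (chains present: %s)",
                       chain_id, paste(unique(at$chain), collapse = ", ")))

  at <- at[at$type == "ATOM" & at$chain == chain_id &
             at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep highest occupancy per (resno, insert, atom); ties -> first
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -at$o,
               seq_len(nrow(at)))  # stable within key: occupancy desc, file order
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]
  at <- at[order(match(paste(at$resno, at$insert, sep = "|"),
                       unique(paste(at$resno, at$insert, sep = "|")))), ,
           drop = FALSE]

  rid <- paste(at$resno, at$insert, sep = "|")
  seen <- unique(rid)
  keep <- character(0)
  dropped <- 0L
  rows <- list()
  for (r in seen) {
    sub <- at[rid == r, , drop = FALSE]
    if (all(c("N", "CA", "C") %in% sub$elety)) {
      keep <- c(keep, r)
      rows[[r]] <- sub
    } else dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(sprintf("chain %s: dropped %d residue(s) missing backbone atoms",
                    chain_id, dropped), call. = FALSE)
  if (length(keep) == 0L)
    stop_pbsvr("pbsvr_empty_chain",
               sprintf("chain '%s': no residues with complete N/CA/C backbone",
                       chain_id))

  get_atom <- function(sub, ety) {
    a <- sub[sub$elety == ety, c("x", "y", "z")][1, ]
    as.numeric(a)
  }
  n <- length(keep)
  Nm <- CAm <- Cm <- matrix(NA_real_, n, 3)
  resno <- integer(n); ins <- character(n); aa <- character(n)
  for (i in seq_len(n)) {
    sub <- rows[[keep[i]]]
    Nm[i, ] <- get_atom(sub, "N")
    CAm[i, ] <- get_atom(sub, "CA")
    Cm[i, ] <- get_atom(sub, "C")
    resno[i] <- sub$resno[1]
    ins[i] <- sub$insert[1]
    aa[i] <- bio3d::aa321(sub$resid[1])
  }
  aa[is.na(aa) | aa == ""] <- "X"
  backbone_chain(chain_id, resno, ins, aa, Nm, CAm, Cm)
}

#' Apply a rigid transform to a coordinate matrix
#'
#' @param coords n x 3 matrix (rows are points).
#' @param transform a `rigid_transform` (see [fit_superposition()]).
#' @return The transformed n x 3 matrix `coords %*% R + t`.
#' @export
apply_transform <- function(coords, transform) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  sweep(coords %*% transform$rotation, 2, transform$translation, `+`)
}

transform_chain <- function(chain, transform) {
  chain$N <- apply_transform(chain$N, transform)
  chain$CA <- apply_transform(chain$CA, transform)
  chain$C <- apply_transform(chain$C, transform)
  chain
}

#' Write a superposed structure pair as a PDB file
#'
#' Writes chain A unchanged and chain B with `transform` applied, as ATOM
#' records (N, CA, C per residue) with coordinates to three decimals.  If the
#' two chains share an identifier, chain B is relabelled "B".
#'
#' @param chainA,chainB [backbone_chain()] objects.
#' @param transform `rigid_transform` applied to chain B.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_superposed <- function(chainA, chainB, transform, path) {
  ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE,
                 error = function(e) FALSE)
  if (!isTRUE(ok))
    stop_pbsvr("pbsvr_unwritable", sprintf("cannot write to %s", path))
  chainB <- transform_chain(chainB, transform)
  idB <- if (identical(chainB$chain_id, chainA$chain_id)) "B" else chainB$chain_id

  flat <- function(ch, id) {
    n <- length(ch)
    idx <- rep(seq_len(n), each = 3)
    ety <- rep(c("N", "CA", "C"), n)
    xyz <- matrix(NA_real_, 3 * n, 3)
    xyz[ety == "N", ] <- ch$N
    xyz[ety == "CA", ] <- ch$CA
    xyz[ety == "C", ] <- ch$C
    list(xyz = round(xyz, 3), ety = ety, resno = ch$resno[idx],
         resid = bio3d::aa123(ch$aa[idx]), chain = rep(id, 3 * n),
         ins = ch$ins[idx])
  }
  a <- flat(chainA, chainA$chain_id)
  b <- flat(chainB, idB)
  xyz <- rbind(a$xyz, b$xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", nrow(xyz)),
    resno = c(a$resno, b$resno),
    resid = c(a$resid, b$resid),
    eleno = seq_len(nrow(xyz)),
    elety = c(a$ety, b$ety),
    chain = c(a$chain, b$chain),
    insert = c(a$ins, b$ins)
  )
  invisible(path)
}

# identity transform helper
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "rigid_transform")
}
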