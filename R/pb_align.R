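# Global dynamic-programming alignment of PB sequences and PB scoring.

PB_ALPHABET <- c(letters[1:16], "Z")

# augment a 16x16 matrix with a Z row/column scoring 0 against everything
augment_z <- function(M) {
  if ("Z" %in% rownames(M)) return(M)
  M2 <- matrix(0, 17, 17, dimnames = list(PB_ALPHABET, PB_ALPHABET))
  M2[rownames(M), colnames(M)] <- M
  M2["Z", ] <- 0; M2[, "Z"] <- 0
  M2
}

encode_letters <- function(s, alphabet) {
  cc <- if (length(s) == 1L && nchar(s[1]) != 1L) chars(s) else s
  code <- match(cc, alphabet)
  if (anyNA(code))
    stop_pbsvr("pbsvr_unknown_letter",
               sprintf("letters outside alphabet: %s",
                       paste(unique(cc[is.na(code)]), collapse = ", ")))
  code
}

#' Global affine-gap alignment of two PB strings
#'
#' Needleman-Wunsch/Gotoh global alignment under a PB substitution matrix
#' with affine gaps: a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.  The unassigned symbol "Z" scores 0
#' against every letter.  Traceback ties are resolved deterministically
#' (diagonal, then gap-in-B, then gap-in-A).
#'
#' @param pbX,pbY ungapped PB strings (single strings or character vectors of
#'   letters) over a..p and "Z"; both non-empty.
#' @param M 16 x 16 [pb_substitution_matrix()].
#' @param gap_open,gap_extend non-positive gap penalties (defaults -5, -0.5).
#' @return A `pb_alignment`: list with gapped `rows` (two strings over the
#'   alphabet plus "-"), `raw_score`, and `aligned_columns` (columns holding
#'   letters in both rows).
#' @export
align_global <- function(pbX, pbY, M = pb_substitution_matrix(),
                         gap_open = -5.0, gap_extend = -0.5) {
  if (gap_open > 0 || gap_extend > 0)
    stop_pbsvr("pbsvr_bad_gap", "gap penalties must be non-positive")
  xs <- if (length(pbX) == 1L) chars(pbX) else pbX
  ys <- if (length(pbY) == 1L) chars(pbY) else pbY
  if (length(xs) == 0L || length(ys) == 0L)
    stop_pbsvr("pbsvr_empty_sequence", "cannot align an empty PB sequence")
  Mz <- augment_z(M)
  xi <- encode_letters(xs, rownames(Mz)) - 1L
  yi <- encode_letters(ys, rownames(Mz)) - 1L
  res <- gotoh_align_cpp(xi, yi, Mz, gap_open, gap_extend)
  rowX <- ifelse(res$ai == 0L, "-", xs[pmax(res$ai, 1L)])
  rowY <- ifelse(res$bi == 0L, "-", ys[pmax(res$bi, 1L)])
  structure(
    list(rows = c(paste(rowX, collapse = ""), paste(rowY, collapse = "")),
         raw_score = res$score,
         aligned_columns = sum(res$ai != 0L & res$bi != 0L),
         ai = res$ai, bi = res$bi),
    class = "pb_alignment"
  )
}

#' @export
print.pb_alignment <- function(x, ...) {
  cat(sprintf("<pb_alignment> score %.3f, %d aligned columns\n%s\n%s\n",
              x$raw_score, x$aligned_columns, x$rows[1], x$rows[2]))
  invisible(x)
}

#' PB score of a gapped PB row pair
#'
#' The raw PB score is the sum of substitution-matrix values over columns
#' where both rows hold a..p letters ("Z" and gaps contribute nothing); the
#' normalized score divides by the number of such columns (undefined, NA,
#' when there are none).
#'
#' @param rowX,rowY equal-length gapped PB strings.
#' @param M 16 x 16 [pb_substitution_matrix()].
#' @return List with `raw`, `normalized` and `aligned_columns`.
#' @export
pb_score <- function(rowX, rowY, M = pb_substitution_matrix()) {
  xs <- chars(rowX); ys <- chars(rowY)
  if (length(xs) != length(ys))
    stop_pbsvr("pbsvr_unequal_rows", "PB rows differ in length")
  both <- xs %in% PB_LETTERS & ys %in% PB_LETTERS
  raw <- if (any(both)) sum(M[cbind(xs[both], ys[both])]) else 0
  n <- sum(both)
  list(raw = raw, normalized = if (n > 0L) raw / n else NA_real_,
       aligned_columns = n)
}
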