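# Per-SVR assessment: PB realignment, before/after metrics, classification.

#' Extract an SVR's ungapped PB substrings
#'
#' Slices the gapped PB rows over the SVR's columns and drops gaps and "Z"
#' symbols, keeping the residue indices of the surviving letters for
#' equivalence bookkeeping.
#'
#' @param aln a [pairwise_alignment()].
#' @param pb_rows gapped PB rows from [project_pbs()].
#' @param region one-row slice of a `region_set` (an SVR).
#' @return List with `pbX`, `pbY` (character vectors, possibly empty) and
#'   `residx_A`, `residx_B` (residue indices of each kept letter).
#' @export
extract_svr_pbs <- function(aln, pb_rows, region) {
  idx <- region$start:region$end
  take <- function(row, map) {
    sym <- chars(row)[idx]
    res <- map[idx]
    keep <- sym %in% PB_LETTERS
    list(pb = sym[keep], residx = res[keep])
  }
  a <- take(pb_rows$pbA, aln$colmapA)
  b <- take(pb_rows$pbB, aln$colmapB)
  list(pbX = a$pb, pbY = b$pb, residx_A = a$residx, residx_B = b$residx)
}

#' SVR realignment eligibility
#'
#' An SVR is realigned only when it carries more than three aligned PBs,
#' read as: the shorter of the two extracted PB substrings has at least
#' `min_pbs` (default 4) letters.  The threshold and the side rule are
#' configurable.
#'
#' @param pbX,pbY extracted PB substrings (character vectors).
#' @param min_pbs minimum PB count (default 4).
#' @param rule "min" (default): the shorter side must reach `min_pbs`;
#'   "both": kept for symmetry, identical criterion stated per side.
#' @return Logical flag.
#' @export
is_eligible <- function(pbX, pbY, min_pbs = 4L, rule = c("min", "both")) {
  rule <- match.arg(rule)
  min(length(pbX), length(pbY)) >= min_pbs
}

#' Assess one structurally variable region
#'
#' Computes before-metrics from the original column equivalences in the
#' global superposition frame, realigns the SVR's PB substrings with
#' [align_global()], computes after-metrics from the realigned residue
#' equivalences (RMSD after local refitting when at least 3 pairs exist,
#' otherwise in the global frame), and classifies the SVR as
#' conformationally similar when the normalized PB score is at least
#' `cutoff` (inclusive; default -0.42).
#'
#' @param chainA,chainB [backbone_chain()] objects.
#' @param aln a [pairwise_alignment()].
#' @param pb_rows gapped PB rows from [project_pbs()].
#' @param region one-row SVR slice of a `region_set` (non-terminal).
#' @param transform global `rigid_transform` for chain B.
#' @param M PB substitution matrix.
#' @param gap_open,gap_extend affine gap penalties.
#' @param cutoff normalized PB score classification cutoff (default -0.42).
#' @param min_pbs eligibility threshold, see [is_eligible()].
#' @param sdm_metric plug-in metric `function(rmsd, n_equiv, lenA, lenB)`;
#'   default [sdm()].
#' @return An `svr_assessment` list: svr_id, start/end columns, lenA/lenB,
#'   eligible, pb_score_raw/norm, class ("similar", "dissimilar",
#'   "not_assessed"), rmsd_before/after, sdm_before/after, local_refit flag
#'   and realigned_rows.
#' @export
assess_svr <- function(chainA, chainB, aln, pb_rows, region, transform,
                       M = pb_substitution_matrix(),
                       gap_open = -5.0, gap_extend = -0.5,
                       cutoff = -0.42, min_pbs = 4L, sdm_metric = sdm) {
  idx <- region$start:region$end
  ia <- aln$colmapA[idx]; ib <- aln$colmapB[idx]
  lenA <- sum(!is.na(ia)); lenB <- sum(!is.na(ib))
  caB <- apply_transform(chainB$CA, transform)

  out <- list(svr_id = region$svr_id, start = region$start, end = region$end,
              lenA = lenA, lenB = lenB, eligible = FALSE,
              pb_score_raw = NA_real_, pb_score_norm = NA_real_,
              class = "not_assessed",
              rmsd_before = NA_real_, rmsd_after = NA_real_,
              sdm_before = NA_real_, sdm_after = NA_real_,
              local_refit = FALSE, realigned_rows = NULL)
  class(out) <- "svr_assessment"

  both <- !is.na(ia) & !is.na(ib)
  if (any(both)) {
    out$rmsd_before <- rmsd_fixed_frame(chainA$CA[ia[both], , drop = FALSE],
                                        caB[ib[both], , drop = FALSE])
    out$sdm_before <- sdm_metric(out$rmsd_before, sum(both), lenA, lenB)
  }

  ext <- extract_svr_pbs(aln, pb_rows, region)
  out$eligible <- is_eligible(ext$pbX, ext$pbY, min_pbs)
  if (!out$eligible) return(out)

  pba <- align_global(ext$pbX, ext$pbY, M, gap_open, gap_extend)
  sc <- pb_score(pba$rows[1], pba$rows[2], M)
  out$pb_score_raw <- sc$raw
  out$pb_score_norm <- sc$normalized
  out$realigned_rows <- pba$rows
  out$class <- if (!is.na(sc$normalized) && sc$normalized >= cutoff)
    "similar" else "dissimilar"

  # realigned residue equivalences: letter-letter columns mapped back
  mm <- pba$ai != 0L & pba$bi != 0L
  ra <- ext$residx_A[pba$ai[mm]]
  rb <- ext$residx_B[pba$bi[mm]]
  if (length(ra) >= 3L) {
    fit <- tryCatch(
      fit_superposition(chainA$CA[ra, , drop = FALSE],
                        chainB$CA[rb, , drop = FALSE]),
      pbsvr_error = function(e) NULL)
    if (!is.null(fit)) {
      out$rmsd_after <- fit$rmsd
      out$local_refit <- TRUE
    }
  }
  if (!out$local_refit && length(ra) >= 1L)
    out$rmsd_after <- rmsd_fixed_frame(chainA$CA[ra, , drop = FALSE],
                                       caB[rb, , drop = FALSE])
  if (length(ra) >= 1L)
    out$sdm_after <- sdm_metric(out$rmsd_after, length(ra), lenA, lenB)
  out
}

#' Merge assessments into an annotated alignment
#'
#' Sets per-column region labels from the SVR classes (terminal SVRs are
#' labelled excluded, ineligible SVRs not-assessed) and bundles alignment,
#' PB rows, regions and assessments into one object for reporting.
#'
#' @param aln a [pairwise_alignment()].
#' @param pb_rows gapped PB rows from [project_pbs()].
#' @param regions a `region_set` (after [exclude_terminal()]).
#' @param assessments list of `svr_assessment` objects, one per non-excluded
#'   SVR, in region order.
#' @return An `annotated_alignment` list.
#' @export
merge_results <- function(aln, pb_rows, regions, assessments) {
  n <- alignment_width(aln)
  labels <- rep("SCR", n)
  by_id <- setNames(assessments,
                    vapply(assessments, function(a) a$svr_id, integer(1)))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$kind != "SVR") next
    lab <- if (r$excluded) "SVR_terminal_excluded" else {
      a <- by_id[[as.character(r$svr_id)]]
      if (is.null(a))
        stop_pbsvr("pbsvr_missing_assessment",
                   sprintf("no assessment for SVR %d", r$svr_id))
      switch(a$class, similar = "SVR_similar", dissimilar = "SVR_dissimilar",
             "SVR_not_assessed")
    }
    labels[r$start:r$end] <- lab
  }
  structure(list(alignment = aln, pb_rows = pb_rows, labels = labels,
                 regions = regions, assessments = assessments),
            class = "annotated_alignment")
}

#' @export
print.annotated_alignment <- function(x, ...) {
  tab <- table(factor(x$labels, levels = names(REGION_SYMBOLS)))
  cat(sprintf("<annotated_alignment> %d columns: %s\n",
              alignment_width(x$alignment),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}
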