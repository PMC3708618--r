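# Pipeline orchestration: full pair-level analysis and the encode stage.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pair analysis.  Defaults are the
#' method's published operating point: SCR distance cutoff 3 Angstrom, SVR
#' minimum run length 3 columns, realignment eligibility 4 PBs on the
#' shorter side, similarity cutoff -0.42 on the normalized PB score, affine
#' gap penalties -5/-0.5.
#'
#' @param scr_max_dist SCR CA-CA distance threshold (Angstrom, > 0).
#' @param svr_min_len minimum SVR run length in columns (>= 1).
#' @param realign_min_pbs minimum PBs on the shorter side for realignment.
#' @param pb_score_cutoff normalized PB score similarity cutoff (inclusive).
#' @param gap_open,gap_extend non-positive affine gap penalties.
#' @param fit_on "all": fit the global superposition on all aligned columns;
#'   "scr_iterative": fit on all, segment, refit on SCR columns only,
#'   resegment (one pass).
#' @param pb_defs_path,sub_matrix_path optional TSV paths overriding the
#'   bundled PB definitions / substitution matrix.
#' @param break_threshold chain-break CA-CA distance (Angstrom).
#' @param seed integer seed recorded in reports (the pair pipeline itself is
#'   deterministic).
#' @return A `pbsvr_config` list.
#' @export
pbsvr_config <- function(scr_max_dist = 3.0, svr_min_len = 3L,
                         realign_min_pbs = 4L, pb_score_cutoff = -0.42,
                         gap_open = -5.0, gap_extend = -0.5,
                         fit_on = c("all", "scr_iterative"),
                         pb_defs_path = NULL, sub_matrix_path = NULL,
                         break_threshold = 4.5, seed = 1L) {
  fit_on <- match.arg(fit_on)
  if (scr_max_dist <= 0) stop_pbsvr("pbsvr_bad_config", "scr_max_dist must be > 0")
  if (svr_min_len < 1L) stop_pbsvr("pbsvr_bad_config", "svr_min_len must be >= 1")
  if (gap_open > 0 || gap_extend > 0)
    stop_pbsvr("pbsvr_bad_config", "gap penalties must be non-positive")
  structure(list(scr_max_dist = scr_max_dist, svr_min_len = as.integer(svr_min_len),
                 realign_min_pbs = as.integer(realign_min_pbs),
                 pb_score_cutoff = pb_score_cutoff,
                 gap_open = gap_open, gap_extend = gap_extend,
                 fit_on = fit_on, pb_defs_path = pb_defs_path,
                 sub_matrix_path = sub_matrix_path,
                 break_threshold = break_threshold, seed = as.integer(seed)),
            class = "pbsvr_config")
}

resolve_chain <- function(x, chain_id, model_index = 1L) {
  if (inherits(x, "backbone_chain")) x
  else read_backbone(x, chain_id, model_index)
}

resolve_alignment <- function(x, chainA, chainB) {
  if (inherits(x, "pairwise_alignment")) x
  else if (identical(x, "identity")) identity_alignment(chainA, chainB)
  else read_pair_fasta(x)
}

check_alignment_matches <- function(aln, chainA, chainB) {
  ung <- function(row) gsub("-", "", row, fixed = TRUE)
  for (side in list(list(row = ung(aln$rowA), seq = chain_sequence(chainA), id = "A"),
                    list(row = ung(aln$rowB), seq = chain_sequence(chainB), id = "B"))) {
    if (side$row != toupper(side$seq)) {
      d <- which(chars(side$row) != chars(toupper(side$seq)))
      stop_pbsvr("pbsvr_sequence_mismatch", sprintf(
        "alignment row %s does not match chain %s sequence (%d residues differ%s%s)",
        side$id, side$id,
        if (nchar(side$row) != nchar(side$seq)) NA_integer_ else length(d),
        if (nchar(side$row) == nchar(side$seq) && length(d))
          "; first at position " else "",
        if (nchar(side$row) == nchar(side$seq) && length(d)) d[1] else ""))
    }
  }
  invisible(TRUE)
}

#' Run the full pair analysis
#'
#' Executes the whole method on one structure pair: read backbones, encode
#' PB sequences, superpose, compute per-column CA distances, segment into
#' SCRs/SVRs, exclude terminal SVRs, realign and classify every eligible
#' SVR, and merge into an annotated alignment.  When `out_dir` is given the
#' annotated flat file, the per-SVR assessment TSV and the superposed PDB
#' are written there.
#'
#' @param structure_a,structure_b structure file paths or
#'   [backbone_chain()] objects.
#' @param chain_a,chain_b chain identifiers (ignored for ready-made chains).
#' @param alignment aligned-FASTA path, a [pairwise_alignment()], or
#'   "identity" for equal-length chains.
#' @param config a [pbsvr_config()].
#' @param out_dir optional output directory.
#' @param prefix output file prefix.
#' @param verbose emit progress/threshold log messages to standard error.
#' @return A `pbsvr_result` list: chains, PB sequences, alignment, global
#'   transform and RMSD, per-column distances, regions, assessments,
#'   `annotated` ([merge_results()] output) and written `paths`.
#' @export
run_pair <- function(structure_a, chain_a = "A", structure_b, chain_b = "A",
                     alignment = "identity", config = pbsvr_config(),
                     out_dir = NULL, prefix = "pair", verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, pbsvr_error = function(e) {
      stop_pbsvr(class(e)[1],
                 sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  say("config: scr_max_dist=%.2f svr_min_len=%d realign_min_pbs=%d cutoff=%.2f gap=(%.2f,%.2f) fit_on=%s",
      config$scr_max_dist, config$svr_min_len, config$realign_min_pbs,
      config$pb_score_cutoff, config$gap_open, config$gap_extend, config$fit_on)

  chainA <- stage("read", resolve_chain(structure_a, chain_a))
  chainB <- stage("read", resolve_chain(structure_b, chain_b))
  say("chain A: %d residues; chain B: %d residues", length(chainA), length(chainB))
  aln <- stage("alignment", resolve_alignment(alignment, chainA, chainB))
  stage("alignment", check_alignment_matches(aln, chainA, chainB))

  defs <- pb_definitions(config$pb_defs_path)
  M <- pb_substitution_matrix(config$sub_matrix_path)
  pbA <- stage("encode", encode_pbs(chainA, defs, config$break_threshold))
  pbB <- stage("encode", encode_pbs(chainB, defs, config$break_threshold))
  pb_rows <- stage("encode", project_pbs(aln, pbA, pbB))

  both <- !is.na(aln$colmapA) & !is.na(aln$colmapB)
  fit_cols <- function(cols) {
    ia <- aln$colmapA[cols]; ib <- aln$colmapB[cols]
    fit_superposition(chainA$CA[ia, , drop = FALSE],
                      chainB$CA[ib, , drop = FALSE])
  }
  fit <- stage("superpose", fit_cols(which(both)))
  dist <- stage("distances", column_distances(aln, chainA, chainB, fit$transform))
  regions <- stage("segment", segment_regions(dist, config$scr_max_dist,
                                              config$svr_min_len))
  if (config$fit_on == "scr_iterative") {
    scr_cols <- unlist(lapply(which(regions$kind == "SCR"), function(i)
      regions$start[i]:regions$end[i]))
    scr_cols <- intersect(scr_cols, which(both))
    if (length(scr_cols) >= 3L) {
      fit <- stage("superpose", fit_cols(scr_cols))
      dist <- stage("distances",
                    column_distances(aln, chainA, chainB, fit$transform))
      regions <- stage("segment", segment_regions(dist, config$scr_max_dist,
                                                  config$svr_min_len))
    }
  }
  regions <- exclude_terminal(regions)
  say("superposition RMSD (fit on %s): %.3f A; %d SCRs, %d SVRs (%d terminal-excluded)",
      config$fit_on, fit$rmsd, sum(regions$kind == "SCR"),
      sum(regions$kind == "SVR"), sum(regions$excluded))

  svr_rows <- which(regions$kind == "SVR" & !regions$excluded)
  assessments <- lapply(svr_rows, function(i)
    stage("assess",
          assess_svr(chainA, chainB, aln, pb_rows, regions[i, ], fit$transform,
                     M, config$gap_open, config$gap_extend,
                     config$pb_score_cutoff, config$realign_min_pbs)))
  for (a in assessments)
    say("SVR %d [%d-%d]: %s (norm score %s; rmsd %s -> %s A)",
        a$svr_id, a$start, a$end, a$class, fmt_num(a$pb_score_norm),
        fmt_num(a$rmsd_before), fmt_num(a$rmsd_after))

  annotated <- stage("merge", merge_results(aln, pb_rows, regions, assessments))

  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p_ann <- file.path(out_dir, paste0(prefix, "_annotated.txt"))
    p_tsv <- file.path(out_dir, paste0(prefix, "_svr.tsv"))
    p_pdb <- file.path(out_dir, paste0(prefix, "_superposed.pdb"))
    stage("write", write_annotated(annotated, p_ann))
    stage("write", write_assessment_tsv(assessments, regions, p_tsv))
    stage("write", write_superposed(chainA, chainB, fit$transform, p_pdb))
    paths <- c(annotated = p_ann, svr_tsv = p_tsv, superposed = p_pdb)
    say("wrote %s, %s, %s", p_ann, p_tsv, p_pdb)
  }

  structure(list(chainA = chainA, chainB = chainB, pbA = pbA, pbB = pbB,
                 alignment = aln, pb_rows = pb_rows, transform = fit$transform,
                 global_rmsd = fit$rmsd, distances = dist, regions = regions,
                 assessments = assessments, annotated = annotated,
                 config = config, paths = paths),
            class = "pbsvr_result")
}

write_assessment_tsv <- function(assessments, regions, path) {
  hdr <- c("svr_id", "columns", "lenA", "lenB", "pb_score_raw",
           "pb_score_norm", "rmsd_before", "rmsd_after", "sdm_before",
           "sdm_after", "class")
  rows <- vapply(assessments, function(a)
    paste(a$svr_id, sprintf("%d-%d", a$start, a$end), a$lenA, a$lenB,
          fmt_num(a$pb_score_raw), fmt_num(a$pb_score_norm),
          fmt_num(a$rmsd_before), fmt_num(a$rmsd_after),
          fmt_num(a$sdm_before), fmt_num(a$sdm_after), a$class,
          sep = "\t"), character(1))
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  invisible(path)
}

#' @export
print.pbsvr_result <- function(x, ...) {
  cat(sprintf("<pbsvr_result> %d columns; global RMSD %.3f A\n",
              alignment_width(x$alignment), x$global_rmsd))
  print(x$annotated)
  for (a in x$assessments)
    cat(sprintf("  SVR %d [%d-%d] %s: norm score %s, RMSD %s -> %s A\n",
                a$svr_id, a$start, a$end, a$class, fmt_num(a$pb_score_norm),
                fmt_num(a$rmsd_before), fmt_num(a$rmsd_after)))
  invisible(x)
}

#' @method summary pbsvr_result
#' @export
summary.pbsvr_result <- function(object, ...) {
  cls <- vapply(object$assessments, `[[`, character(1), "class")
  structure(list(columns = alignment_width(object$alignment),
                 global_rmsd = object$global_rmsd,
                 n_scr = sum(object$regions$kind == "SCR"),
                 n_svr = sum(object$regions$kind == "SVR"),
                 n_excluded = sum(object$regions$excluded),
                 n_similar = sum(cls == "similar"),
                 n_dissimilar = sum(cls == "dissimilar"),
                 n_not_assessed = sum(cls == "not_assessed")),
            class = "summary.pbsvr_result")
}

#' @export
print.summary.pbsvr_result <- function(x, ...) {
  cat(sprintf(paste0("pair summary: %d columns, global RMSD %.3f A\n",
                     "  SCRs: %d  SVRs: %d (terminal-excluded: %d)\n",
                     "  similar: %d  dissimilar: %d  not assessed: %d\n"),
              x$columns, x$global_rmsd, x$n_scr, x$n_svr, x$n_excluded,
              x$n_similar, x$n_dissimilar, x$n_not_assessed))
  invisible(x)
}

#' Encode one structure as a PB sequence file
#'
#' Reads a chain, encodes it as PB letters and (optionally) writes a
#' single-record FASTA.
#'
#' @param structure structure file path or [backbone_chain()].
#' @param chain_id chain identifier.
#' @param config a [pbsvr_config()].
#' @param out optional output FASTA path.
#' @return The PB string, invisibly when `out` is given.
#' @export
run_encode <- function(structure, chain_id = "A", config = pbsvr_config(),
                       out = NULL) {
  chain <- resolve_chain(structure, chain_id)
  pb <- paste(encode_pbs(chain, pb_definitions(config$pb_defs_path),
                         config$break_threshold), collapse = "")
  if (!is.null(out)) {
    writeLines(c(sprintf(">%s_%s_PB", if (is.character(structure))
      basename(structure) else "chain", chain$chain_id), pb), out)
    return(invisible(pb))
  }
  pb
}
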