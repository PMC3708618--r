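# Pairwise structure-based sequence alignments: representation, FASTA input,
# PB projection, and the annotated flat-file writer/reader.

#' Pairwise alignment objects
#'
#' A `pairwise_alignment` holds two gapped rows of equal length plus column
#' maps giving, per column, the 1-based residue index in each chain (NA at
#' gaps).  No column may be gapped in both rows.
#'
#' @param rowA,rowB gapped strings of equal length; "." is normalized to "-"
#'   and letters to uppercase.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(rowA, rowB) {
  norm <- function(s) toupper(gsub(".", "-", s, fixed = TRUE))
  rowA <- norm(rowA); rowB <- norm(rowB)
  if (nchar(rowA) != nchar(rowB))
    stop_pbsvr("pbsvr_unequal_rows",
               sprintf("aligned rows differ in length (%d vs %d)",
                       nchar(rowA), nchar(rowB)))
  if (nchar(rowA) == 0L)
    stop_pbsvr("pbsvr_empty_alignment", "empty alignment")
  ca <- chars(rowA); cb <- chars(rowB)
  if (any(ca == "-" & cb == "-"))
    stop_pbsvr("pbsvr_all_gap_column", "alignment contains an all-gap column")
  mkmap <- function(cc) {
    m <- rep(NA_integer_, length(cc))
    m[cc != "-"] <- seq_len(sum(cc != "-"))
    m
  }
  structure(list(rowA = rowA, rowB = rowB,
                 colmapA = mkmap(ca), colmapB = mkmap(cb)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns\nA: %s\nB: %s\n",
              nchar(x$rowA), x$rowA, x$rowB))
  invisible(x)
}

alignment_width <- function(aln) nchar(aln$rowA)

#' Identity alignment for equal-length chains
#'
#' @param chainA,chainB [backbone_chain()] objects of equal length.
#' @return A gapless [pairwise_alignment()] pairing residue i with residue i.
#' @export
identity_alignment <- function(chainA, chainB) {
  if (length(chainA) != length(chainB))
    stop_pbsvr("pbsvr_unequal_rows",
               "identity alignment needs equal-length chains")
  pairwise_alignment(chain_sequence(chainA), chain_sequence(chainB))
}

#' Read a two-record aligned FASTA
#'
#' The file must hold exactly two aligned records of equal length; "." and
#' "-" are both accepted as gaps.
#'
#' @param path aligned FASTA path.
#' @return A [pairwise_alignment()].
#' @export
read_pair_fasta <- function(path) {
  if (!file.exists(path))
    stop_pbsvr("pbsvr_missing_file", sprintf("alignment file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop_pbsvr("pbsvr_bad_record_count",
               sprintf("expected exactly 2 aligned records, found %d",
                       length(recs)))
  pairwise_alignment(as.character(recs[[1]]), as.character(recs[[2]]))
}

#' Project per-residue PB sequences onto alignment columns
#'
#' Places each chain's PB letter at its column via the column maps and "-"
#' at gap columns, yielding gapped PB rows sharing the alignment's gap
#' structure.
#'
#' @param aln a [pairwise_alignment()].
#' @param pbA,pbB per-residue PB symbol vectors (from [encode_pbs()]); the
#'   length must equal the respective chain length implied by the alignment.
#' @return A list with gapped strings `pbA` and `pbB`.
#' @export
project_pbs <- function(aln, pbA, pbB) {
  nA <- max(aln$colmapA, 0, na.rm = TRUE)
  nB <- max(aln$colmapB, 0, na.rm = TRUE)
  if (length(pbA) != nA || length(pbB) != nB)
    stop_pbsvr("pbsvr_length_mismatch",
               "PB sequence length does not match aligned chain length")
  proj <- function(map, pb) {
    out <- rep("-", length(map))
    out[!is.na(map)] <- pb[map[!is.na(map)]]
    paste(out, collapse = "")
  }
  list(pbA = proj(aln$colmapA, pbA), pbB = proj(aln$colmapB, pbB))
}

# region label -> region-line symbol
REGION_SYMBOLS <- c(SCR = "=", SVR_similar = "s", SVR_dissimilar = "d",
                    SVR_terminal_excluded = "x", SVR_not_assessed = "n")

#' Write an annotated alignment flat file
#'
#' Emits repeated 60-column blocks of five lines (amino-acid row A, PB row
#' A, PB row B, amino-acid row B, region line), with SCR columns in
#' uppercase and SVR columns in lowercase, followed by a footer of region
#' intervals and per-SVR assessment records (TSV).  Region-line symbols:
#' "=" SCR, "s" similar SVR, "d" dissimilar SVR, "x" terminal-excluded SVR,
#' "n" SVR not assessed (too few aligned PBs).
#'
#' @param ann an `annotated_alignment` from [merge_results()].
#' @param path output path.
#' @param width block width in columns (default 60).
#' @return Invisibly, `path`.
#' @export
write_annotated <- function(ann, path, width = 60L) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_pbsvr("pbsvr_unwritable", sprintf("cannot write to %s", path)))
  on.exit(close(con))
  aln <- ann$alignment
  lab <- ann$labels
  sym <- REGION_SYMBOLS[lab]
  is_svr <- lab != "SCR"
  ca <- chars(aln$rowA); cb <- chars(aln$rowB)
  ca <- ifelse(is_svr & ca != "-", tolower(ca), toupper(ca))
  cb <- ifelse(is_svr & cb != "-", tolower(cb), toupper(cb))
  pa <- chars(ann$pb_rows$pbA); pb <- chars(ann$pb_rows$pbB)
  n <- length(ca)
  writeLines("# pbsvr annotated alignment v1", con)
  writeLines(sprintf("# columns: %d", n), con)
  for (start in seq(1L, n, by = width)) {
    end <- min(start + width - 1L, n)
    idx <- start:end
    writeLines(sprintf("AA_A %s", paste(ca[idx], collapse = "")), con)
    writeLines(sprintf("PB_A %s", paste(pa[idx], collapse = "")), con)
    writeLines(sprintf("PB_B %s", paste(pb[idx], collapse = "")), con)
    writeLines(sprintf("AA_B %s", paste(cb[idx], collapse = "")), con)
    writeLines(sprintf("RGN  %s", paste(sym[idx], collapse = "")), con)
    writeLines("", con)
  }
  reg <- ann$regions
  writeLines("# regions: kind start end terminal", con)
  for (i in seq_len(nrow(reg)))
    writeLines(sprintf("REGION\t%s\t%d\t%d\t%d", reg$kind[i], reg$start[i],
                       reg$end[i], as.integer(reg$terminal[i])), con)
  writeLines(paste0("# svr records: svr_id columns lenA lenB pb_score_raw ",
                    "pb_score_norm rmsd_before rmsd_after sdm_before ",
                    "sdm_after class row_a row_b"), con)
  for (a in ann$assessments) {
    writeLines(sprintf("SVR\t%d\t%d-%d\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                       a$svr_id, a$start, a$end, a$lenA, a$lenB,
                       fmt_num(a$pb_score_raw), fmt_num(a$pb_score_norm),
                       fmt_num(a$rmsd_before), fmt_num(a$rmsd_after),
                       fmt_num(a$sdm_before), fmt_num(a$sdm_after),
                       a$class,
                       a$realigned_rows[1] %||% ".",
                       a$realigned_rows[2] %||% "."), con)
  }
  invisible(path)
}

fmt_num <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) "NA" else sprintf("%.4f", x)
}

#' Read back an annotated alignment flat file
#'
#' Parses a file written by [write_annotated()]; used for round-tripping and
#' downstream scripting.
#'
#' @param path file path.
#' @return A list with `alignment`, `pb_rows`, `labels`, `regions`
#'   (data.frame) and `svr_records` (data.frame).
#' @export
read_annotated <- function(path) {
  if (!file.exists(path))
    stop_pbsvr("pbsvr_missing_file", sprintf("file not found: %s", path))
  ln <- readLines(path)
  grab <- function(tag) {
    rows <- ln[startsWith(ln, paste0(tag, " "))]
    paste(sub("^.{5}", "", rows), collapse = "")
  }
  aa_a <- grab("AA_A"); aa_b <- grab("AA_B")
  pb_a <- grab("PB_A"); pb_b <- grab("PB_B")
  rgn <- grab("RGN ")
  sym2lab <- setNames(names(REGION_SYMBOLS), REGION_SYMBOLS)
  labels <- unname(sym2lab[chars(rgn)])
  reg_rows <- ln[startsWith(ln, "REGION\t")]
  regions <- if (length(reg_rows)) {
    p <- do.call(rbind, strsplit(reg_rows, "\t", fixed = TRUE))
    data.frame(kind = p[, 2], start = as.integer(p[, 3]),
               end = as.integer(p[, 4]), terminal = p[, 5] == "1",
               stringsAsFactors = FALSE)
  } else NULL
  svr_rows <- ln[startsWith(ln, "SVR\t")]
  svr <- if (length(svr_rows)) {
    p <- do.call(rbind, strsplit(svr_rows, "\t", fixed = TRUE))
    data.frame(svr_id = as.integer(p[, 2]), columns = p[, 3],
               lenA = as.integer(p[, 4]), lenB = as.integer(p[, 5]),
               pb_score_raw = suppressWarnings(as.numeric(p[, 6])),
               pb_score_norm = suppressWarnings(as.numeric(p[, 7])),
               rmsd_before = suppressWarnings(as.numeric(p[, 8])),
               rmsd_after = suppressWarnings(as.numeric(p[, 9])),
               sdm_before = suppressWarnings(as.numeric(p[, 10])),
               sdm_after = suppressWarnings(as.numeric(p[, 11])),
               class = p[, 12], row_a = p[, 13], row_b = p[, 14],
               stringsAsFactors = FALSE)
  } else NULL
  list(alignment = pairwise_alignment(aa_a, aa_b),
       pb_rows = list(pbA = pb_a, pbB = pb_b),
       labels = labels, regions = regions, svr_records = svr)
}
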