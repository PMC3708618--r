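test_that("read_pair_fasta builds column maps and normalizes gaps", {
  path <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">a", "AC-E", ">b", "ACDE"), path)
  aln <- read_pair_fasta(path)
  expect_equal(aln$colmapA, c(1L, 2L, NA, 3L))
  expect_equal(aln$colmapB, 1:4)
  writeLines(c(">a", "AC.E", ">b", "acde"), path)  # dots and case normalized
  aln2 <- read_pair_fasta(path)
  expect_identical(aln2$rowA, "AC-E")
  expect_identical(aln2$rowB, "ACDE")
})

test_that("malformed pair FASTA raises the contracted errors", {
  path <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK"), path)
  expect_error(read_pair_fasta(path), class = "pbsvr_unequal_rows")
  writeLines(c(">a", "ACDE", ">b", "ACDE", ">c", "ACDE"), path)
  expect_error(read_pair_fasta(path), class = "pbsvr_bad_record_count")
  writeLines(c(">a", "AC-E", ">b", "AC-E"), path)
  expect_error(read_pair_fasta(path), class = "pbsvr_all_gap_column")
})

test_that("project_pbs places letters by column map and gaps elsewhere", {
  aln <- pairwise_alignment("AAAAA", "AAAAA")
  pr <- project_pbs(aln, c("Z", "Z", "m", "Z", "Z"), c("Z", "Z", "k", "Z", "Z"))
  expect_identical(pr$pbA, "ZZmZZ")
  aln2 <- pairwise_alignment("AA-AA", "AAAAA")
  pr2 <- project_pbs(aln2, rep("m", 4), rep("k", 5))
  expect_identical(pr2$pbA, "mm-mm")
  expect_error(project_pbs(aln2, rep("m", 5), rep("k", 5)),
               class = "pbsvr_length_mismatch")
})

test_that("ungapping projected PB rows recovers the PB sequences", {
  set.seed(23)
  for (rep in 1:10) {
    nA <- sample(5:12, 1); nB <- sample(5:12, 1)
    pbA <- sample(c(letters[1:16], "Z"), nA, replace = TRUE)
    pbB <- sample(c(letters[1:16], "Z"), nB, replace = TRUE)
    # random alignment: interleave residues and gaps
    ops <- sample(c(rep("M", min(nA, nB)), rep("A", nA - min(nA, nB)),
                    rep("B", nB - min(nA, nB))))
    rowA <- rowB <- character(0)
    for (o in ops) {
      rowA <- c(rowA, if (o %in% c("M", "A")) "X" else "-")
      rowB <- c(rowB, if (o %in% c("M", "B")) "X" else "-")
    }
    aln <- pairwise_alignment(paste(rowA, collapse = ""),
                              paste(rowB, collapse = ""))
    pr <- project_pbs(aln, pbA, pbB)
    expect_identical(gsub("-", "", pr$pbA, fixed = TRUE),
                     paste(pbA, collapse = ""))
    expect_identical(gsub("-", "", pr$pbB, fixed = TRUE),
                     paste(pbB, collapse = ""))
  }
})

test_that("annotated flat file round-trips labels, regions and scores", {
  pair <- make_homolog_pair(loop_recipe("rigid_rotate_loop"), seed = 3)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotated(res$annotated, path)
  back <- read_annotated(path)
  expect_identical(back$labels, res$annotated$labels)
  expect_identical(back$alignment$rowA, res$alignment$rowA)
  expect_identical(back$alignment$colmapB, res$alignment$colmapB)
  reg <- res$regions
  expect_equal(back$regions$start, reg$start)
  expect_equal(back$regions$end, reg$end)
  expect_equal(back$regions$terminal, reg$terminal)
  a <- res$assessments[[1]]
  expect_identical(back$svr_records$class, a$class)
  expect_equal(back$svr_records$pb_score_norm, a$pb_score_norm,
               tolerance = 1e-4)
  expect_equal(back$svr_records$rmsd_after, a$rmsd_after, tolerance = 1e-3)
})

test_that("region labels tile the alignment and render per the format", {
  pair <- make_homolog_pair(loop_recipe("none"), seed = 1)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  expect_true(all(res$annotated$labels == "SCR"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotated(res$annotated, path)
  ln <- readLines(path)
  rgn <- paste(sub("^RGN  ", "", ln[startsWith(ln, "RGN  ")]), collapse = "")
  expect_identical(rgn, strrep("=", alignment_width <- nchar(res$alignment$rowA)))
  aa <- paste(sub("^AA_A ", "", ln[startsWith(ln, "AA_A ")]), collapse = "")
  expect_identical(aa, toupper(aa))  # all-SCR alignment is fully uppercase
})
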