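test_that("SVR PB substrings are extracted without gaps or Z", {
  aln <- pairwise_alignment("AA-A", "AAAA")
  region <- data.frame(start = 1L, end = 4L, svr_id = 1L, kind = "SVR")
  ext <- extract_svr_pbs(aln, list(pbA = "mm-k", pbB = "mmmk"), region)
  expect_identical(paste(ext$pbX, collapse = ""), "mmk")
  expect_identical(paste(ext$pbY, collapse = ""), "mmmk")
  # residue bookkeeping: indices follow the column maps
  expect_equal(ext$residx_A, c(1L, 2L, 3L))
  expect_equal(ext$residx_B, 1:4)
  # Z symbols are dropped too, and an all-gap/Z side comes back empty
  aln2 <- pairwise_alignment("AA-A-", "AAAAA")
  extz <- extract_svr_pbs(aln2, list(pbA = "mZ-k-", pbB = "mmmkZ"),
                          data.frame(start = 1L, end = 5L, svr_id = 1L))
  expect_identical(paste(extz$pbX, collapse = ""), "mk")
  expect_identical(paste(extz$pbY, collapse = ""), "mmmk")
  exte <- extract_svr_pbs(aln2, list(pbA = "ZZ-Z-", pbB = "mmmkZ"),
                          data.frame(start = 1L, end = 5L, svr_id = 1L))
  expect_length(exte$pbX, 0L)
  expect_false(is_eligible(exte$pbX, exte$pbY))
})

test_that("extracted substrings are substrings of the chain PB sequences", {
  pair <- make_homolog_pair(loop_recipe("rigid_rotate_loop"), seed = 19)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  reg <- res$regions[res$regions$kind == "SVR" & !res$regions$excluded, ]
  for (i in seq_len(nrow(reg))) {
    ext <- extract_svr_pbs(res$alignment, res$pb_rows, reg[i, ])
    expect_true(grepl(paste(ext$pbX, collapse = ""),
                      paste(res$pbA, collapse = ""), fixed = TRUE))
    expect_true(grepl(paste(ext$pbY, collapse = ""),
                      paste(res$pbB, collapse = ""), fixed = TRUE))
  }
})

test_that("eligibility requires more than three PBs on the shorter side", {
  expect_true(is_eligible(rep("m", 4), rep("m", 7)))
  expect_false(is_eligible(rep("m", 3), rep("m", 9)))
  expect_false(is_eligible(character(0), rep("m", 5)))
})

test_that("a normalized score exactly at the cutoff classifies as similar", {
  # constant matrix: every aligned pair scores exactly -0.42, so any gapless
  # realignment has normalized score -0.42 -> inclusive bound -> similar
  M <- const_matrix(-0.42)
  pair <- make_homolog_pair(loop_recipe("rigid_rotate_loop"), seed = 3)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  reg <- res$regions[res$regions$kind == "SVR" & !res$regions$excluded, ][1, ]
  a <- assess_svr(res$chainA, res$chainB, res$alignment, res$pb_rows, reg,
                  res$transform, M)
  expect_equal(a$pb_score_norm, -0.42)
  expect_identical(a$class, "similar")
  # and infinitesimally below the cutoff -> dissimilar
  a2 <- assess_svr(res$chainA, res$chainB, res$alignment, res$pb_rows, reg,
                   res$transform, const_matrix(-0.43))
  expect_identical(a2$class, "dissimilar")
})

test_that("identical PB substrings classify similar under a dominant diagonal", {
  pair <- make_homolog_pair(loop_recipe("rigid_rotate_loop"), seed = 5)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  a <- res$assessments[[1]]
  expect_identical(a$class, "similar")
  expect_gte(a$pb_score_norm, -0.42)
  # local refit of a rigid-rotated loop is exact
  expect_true(a$local_refit)
  expect_lt(a$rmsd_after, 1e-6)
  expect_gt(a$rmsd_before, 3)
})

test_that("classification is monotone in the cutoff", {
  pair <- make_homolog_pair(loop_recipe("change_dihedrals"), seed = 29)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  reg <- res$regions[res$regions$kind == "SVR" & !res$regions$excluded, ][1, ]
  cuts <- c(-10, -3, -0.42, 0, 5)
  cls <- vapply(cuts, function(ct)
    assess_svr(res$chainA, res$chainB, res$alignment, res$pb_rows, reg,
               res$transform, pb_substitution_matrix(), cutoff = ct)$class,
    character(1))
  sim <- cls == "similar"
  expect_true(all(diff(as.integer(sim)) <= 0))  # lowering cutoff only adds
})

test_that("merge_results labels match regions and excluded SVRs are absent", {
  pair <- make_homolog_pair(
    pair_recipe(c(rep(-120, 12), rep(-65, 8), rep(-120, 12), rep(-65, 8),
                  rep(-120, 12)),
                c(rep(130, 12), rep(-38, 8), rep(130, 12), rep(-38, 8),
                  rep(130, 12)),
                list(list(kind = "rigid_rotate_loop", start = 13L, end = 20L,
                          angle = 150),
                     list(kind = "change_dihedrals", start = 33L, end = 40L))),
    seed = 2)
  res <- run_pair(pair$chainA, structure_b = pair$chainB,
                  alignment = pair$alignment, verbose = FALSE)
  ann <- res$annotated
  # label runs agree with region intervals
  for (i in seq_len(nrow(res$regions))) {
    r <- res$regions[i, ]
    expect_equal(length(unique(ann$labels[r$start:r$end])), 1L)
  }
  cls <- vapply(res$assessments, `[[`, character(1), "class")
  expect_true("similar" %in% cls && "dissimilar" %in% cls)
  expect_true(all(c("SVR_similar", "SVR_dissimilar") %in% ann$labels))
  # excluded SVRs never carry an assessment
  ids <- vapply(res$assessments, `[[`, integer(1), "svr_id")
  excl <- res$regions$svr_id[res$regions$excluded]
  expect_length(intersect(ids, excl), 0L)
})

test_that("refit rmsd never exceeds the fixed-frame rmsd on the same pairs", {
  set.seed(37)
  A <- matrix(rnorm(30), 10, 3)
  B <- A + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_lte(fit_superposition(A, B)$rmsd, rmsd_fixed_frame(A, B) + 1e-12)
})
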