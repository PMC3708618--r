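test_that("identity pair fits to the identity transform", {
  A <- build_backbone(rep(-57, 8), rep(-47, 8))$CA
  f <- fit_superposition(A, A)
  expect_lt(max(abs(f$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(f$transform$translation)), 1e-9)
  expect_lt(f$rmsd, 1e-9)
})

test_that("constructed rigid transforms are recovered", {
  set.seed(17)
  for (rep in 1:20) {
    A <- matrix(rnorm(24), 8, 3)
    R <- random_rotation(); t <- rnorm(3, sd = 5)
    B <- A %*% R + matrix(rep(t, each = 8), 8)
    # transform mapping B back onto A must invert (R, t)
    f <- fit_superposition(A, B)
    expect_lt(f$rmsd, 1e-9)
    expect_lt(max(abs(f$transform$rotation - t(R))), 1e-6)
    expect_lt(max(abs(apply_transform(B, f$transform) - A)), 1e-6)
    expect_equal(det(f$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("reflections are rejected: mirror images keep positive rmsd", {
  chiral <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  mirror <- chiral; mirror[, 3] <- -mirror[, 3]
  f <- fit_superposition(chiral, mirror)
  expect_gt(f$rmsd, 0.1)
  expect_equal(det(f$transform$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(fit_superposition(line, line),
               class = "pbsvr_degenerate_geometry")
  expect_error(fit_superposition(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "pbsvr_degenerate_geometry")
})

test_that("rmsd_fixed_frame equals the explicit per-point computation", {
  A <- matrix(0, 4, 3)
  B <- sweep(A, 2, c(3, 4, 0), `+`)
  expect_equal(rmsd_fixed_frame(A, B), 5)
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3); Y <- matrix(rnorm(30), 10, 3)
  manual <- sqrt(mean(sapply(1:10, function(i) sum((X[i, ] - Y[i, ])^2))))
  expect_equal(rmsd_fixed_frame(X, Y), manual)
  expect_error(rmsd_fixed_frame(X, Y[1:9, ]), class = "pbsvr_length_mismatch")
})

test_that("fitted rmsd is optimal and refitting after applying is identity", {
  set.seed(3)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  f <- fit_superposition(A, B)
  # any rigid pre-transform of B cannot beat the fitted rmsd
  for (rep in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    Bp <- B %*% R + matrix(rep(t, each = 12), 12)
    expect_gte(rmsd_fixed_frame(A, Bp) + 1e-12, f$rmsd)
  }
  Bfit <- apply_transform(B, f$transform)
  f2 <- fit_superposition(A, Bfit)
  expect_lt(max(abs(f2$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(f2$transform$translation)), 1e-6)
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(21)
  A <- matrix(rnorm(30), 10, 3)
  B <- A %*% random_rotation() + matrix(rep(c(2, -1, 4), each = 10), 10) +
    matrix(rnorm(30, sd = 0.4), 10, 3)
  f <- fit_superposition(A, B)
  ref <- bio3d::fit.xyz(as.numeric(t(A)), as.numeric(t(B)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  # bio3d::rmsd prints to 3 decimals
  expect_equal(f$rmsd, bio3d::rmsd(as.numeric(t(A)), ref), tolerance = 1e-3)
})

test_that("column distances respect gaps and joint rigid motions", {
  pair <- make_homolog_pair(loop_recipe("delete"), seed = 13)
  aln <- pair$alignment
  both <- !is.na(aln$colmapA) & !is.na(aln$colmapB)
  f <- fit_superposition(pair$chainA$CA[aln$colmapA[both], ],
                         pair$chainB$CA[aln$colmapB[both], ])
  d <- column_distances(aln, pair$chainA, pair$chainB, f$transform)
  expect_true(all(is.na(d[!both])))
  expect_true(all(!is.na(d[both])))
  # joint rigid motion of chain A, refit -> identical distances
  R <- random_rotation(); t <- c(5, 5, -5)
  chA2 <- pair$chainA
  for (a in c("N", "CA", "C"))
    chA2[[a]] <- chA2[[a]] %*% R + matrix(rep(t, each = nrow(chA2[[a]])),
                                          nrow(chA2[[a]]))
  f2 <- fit_superposition(chA2$CA[aln$colmapA[both], ],
                          pair$chainB$CA[aln$colmapB[both], ])
  d2 <- column_distances(aln, chA2, pair$chainB, f2$transform)
  expect_equal(d2, d, tolerance = 1e-6)
})

test_that("identity self-alignment has all-zero column distances", {
  ch <- build_backbone(rep(-57, 10), rep(-47, 10))
  aln <- identity_alignment(ch, ch)
  d <- column_distances(aln, ch, ch, pbsvr:::identity_transform())
  expect_true(all(d < 1e-12))
})

test_that("sdm is zero for identical fragments and monotone in rmsd", {
  expect_equal(sdm(0, 7, 7, 7), 0)
  r <- seq(0, 10, by = 0.5)
  v <- vapply(r, sdm, numeric(1), n_equiv = 7, lenA = 7, lenB = 7)
  expect_true(all(diff(v) > 0))
  # fewer equivalenced residues at equal rmsd -> larger dissimilarity
  expect_gt(sdm(2, 4, 8, 8), sdm(2, 8, 8, 8))
  expect_error(sdm(1, 0, 5, 5), class = "pbsvr_empty_equivalence")
})
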