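test_that("PDB write/read round trip preserves residues and coordinates", {
  ch <- build_backbone(rep(-57, 8), rep(-47, 8))
  path <- withr::local_tempfile(fileext = ".pdb")
  pbsvr:::write_chain_pdb(ch, path)
  back <- read_backbone(path, "A")
  expect_equal(length(back), 8L)
  expect_equal(back$resno, ch$resno)
  for (a in c("N", "CA", "C"))
    expect_lt(max(abs(back[[a]] - ch[[a]])), 1e-3)
})

test_that("residues missing a backbone atom are dropped with a warning", {
  ch <- build_backbone(rep(-57, 6), rep(-47, 6))
  path <- withr::local_tempfile(fileext = ".pdb")
  pbsvr:::write_chain_pdb(ch, path)
  ln <- readLines(path)
  drop <- grepl("^ATOM", ln) & substr(ln, 13, 16) == " C  " &
    substr(ln, 23, 26) == "   3"
  expect_equal(sum(drop), 1L)
  writeLines(ln[!drop], path)
  expect_warning(back <- read_backbone(path, "A"), "dropped 1 residue")
  expect_equal(length(back), 5L)
  expect_false(3L %in% back$resno)
})

test_that("unknown chain and missing file raise distinct errors", {
  ch <- build_backbone(rep(-57, 5), rep(-47, 5))
  path <- withr::local_tempfile(fileext = ".pdb")
  pbsvr:::write_chain_pdb(ch, path)
  expect_error(read_backbone(path, "Z"), class = "pbsvr_unknown_chain")
  expect_error(read_backbone(file.path(tempdir(), "nope.pdb"), "A"),
               class = "pbsvr_missing_file")
})

test_that("write_superposed applies the transform exactly", {
  ch <- build_backbone(rep(-120, 6), rep(130, 6))
  path <- withr::local_tempfile(fileext = ".pdb")
  # identity: chain B coordinates unchanged
  write_superposed(ch, ch, pbsvr:::identity_transform(), path)
  b <- read_backbone(path, "B")
  expect_lt(max(abs(b$CA - ch$CA)), 1e-3)
  # pure translation (1, 0, 0): every B x-coordinate shifted by +1
  tr <- structure(list(rotation = diag(3), translation = c(1, 0, 0)),
                  class = "rigid_transform")
  write_superposed(ch, ch, tr, path)
  b <- read_backbone(path, "B")
  expect_lt(max(abs(b$CA - sweep(ch$CA, 2, c(1, 0, 0), `+`))), 1e-3)
})

test_that("RMSD recomputed from a written pair matches in-memory RMSD", {
  set.seed(5)
  chA <- build_backbone(rep(-57, 10), rep(-47, 10))
  chB <- chA
  R <- random_rotation()
  for (a in c("N", "CA", "C"))
    chB[[a]] <- chB[[a]] %*% R + matrix(rep(c(4, -2, 1), each = 10), 10)
  chB$CA <- chB$CA + matrix(rnorm(30, sd = 0.3), 10)
  fit <- fit_superposition(chA$CA, chB$CA)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_superposed(chA, chB, fit$transform, path)
  a2 <- read_backbone(path, "A"); b2 <- read_backbone(path, "B")
  expect_equal(rmsd_fixed_frame(a2$CA, b2$CA), fit$rmsd, tolerance = 1e-2)
})

test_that("mmCIF input is accepted", {
  ch <- build_backbone(rep(-57, 6), rep(-47, 6))
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  pbsvr:::write_chain_pdb(ch, pdb_path)
  # minimal standard-order PDBx/mmCIF atom_site loop built in code
  cif_path <- withr::local_tempfile(fileext = ".cif")
  ety <- rep(c("N", "CA", "C"), 6)
  ri <- rep(1:6, each = 3)
  xyz <- do.call(rbind, lapply(seq_len(6), function(i)
    rbind(ch$N[i, ], ch$CA[i, ], ch$C[i, ])))
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  lines <- c("data_synth", "#", "loop_", paste0("_atom_site.", fields),
             sprintf("ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A %s 1",
                     seq_len(18), substr(ety, 1, 1), ety, ri,
                     xyz[, 1], xyz[, 2], xyz[, 3], ri, ety), "#")
  suppressWarnings(writeLines(lines, cif_path))
  back <- suppressWarnings(read_backbone(cif_path, "A"))
  expect_equal(length(back), 6L)
  expect_lt(max(abs(back$CA - ch$CA)), 1e-3)
})
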