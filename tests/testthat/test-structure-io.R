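TOY_PDB <- c(
  "HEADER    TOY STRUCTURE",
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.50           C",
  "HETATM    3  O   HOH A   2       9.000   1.000   2.500  0.80 10.00           O",
  "END")

test_that("PDB ATOM/HETATM records parse with exact fixed-point coordinates", {
  arr <- read_pdb(TOY_PDB)
  expect_equal(n_atoms(arr), 3L)
  expect_identical(arr$hetero, c(FALSE, FALSE, TRUE))
  expect_identical(arr$atom_name, c("N", "CA", "O"))
  expect_identical(arr$res_name, c("ALA", "ALA", "HOH"))
  expect_identical(arr$res_id, c(1L, 1L, 2L))
  expect_equal(arr$coord[1, ], c(11.104, 6.134, -6.504))
  expect_equal(arr$occupancy, c(1, 1, 0.8))
  expect_equal(arr$b_factor, c(0, 0.5, 10))
})

test_that("multi-MODEL files produce a stack; inconsistent models error", {
  lines <- c("MODEL        1", TOY_PDB[2:4], "ENDMDL",
             "MODEL        2", TOY_PDB[2:4], "ENDMDL", "END")
  st <- read_pdb(lines)
  expect_s3_class(st, "atom_array_stack")
  expect_equal(n_models(st), 2L)
  expect_equal(n_atoms(st), 3L)
  bad <- c("MODEL        1", TOY_PDB[2:4], "ENDMDL",
           "MODEL        2", TOY_PDB[2:3], "ENDMDL")
  expect_error(read_pdb(bad), "differ in atom count")
})

test_that("PDB errors carry the offending line", {
  bad <- TOY_PDB
  bad[2] <- paste0(substr(bad[2], 1, 30), "  bad.xyz", substr(bad[2], 39, 80))
  expect_error(read_pdb(bad), "line 2")
  expect_error(read_pdb("HEADER    EMPTY"), "no ATOM/HETATM")
  short <- c("ATOM      1  N   ALA A   1      11.104")
  expect_error(read_pdb(short), "54 columns")
})

test_that("PDB write -> read reproduces annotations and coordinates", {
  arr <- random_structure(100, seed = 31)
  back <- read_pdb(write_pdb(arr))
  expect_same_annotations(back, arr)
  expect_coords_equal(back, arr, tol = 5e-4 + 1e-9)
  expect_equal(back$b_factor, arr$b_factor, tolerance = 5e-3)
  expect_equal(back$occupancy, arr$occupancy, tolerance = 5e-3)
  # stacks produce MODEL/ENDMDL blocks
  st <- random_stack(20, 3, seed = 32)
  txt <- write_pdb(st)
  expect_equal(sum(startsWith(txt, "MODEL")), 3L)
  expect_equal(sum(startsWith(txt, "ENDMDL")), 3L)
  back2 <- read_pdb(txt)
  expect_equal(n_models(back2), 3L)
  expect_coords_equal(back2, st, tol = 5e-4 + 1e-9)
})

test_that("PDB field overflow errors name the atom and field", {
  arr <- random_structure(3, seed = 33)
  arr$chain_id <- c("AB", "A", "A")
  expect_error(write_pdb(arr), "chain id")
  arr2 <- random_structure(3, seed = 33)
  arr2$res_id <- c(1L, 2L, 100000L)
  expect_error(write_pdb(arr2), "residue number")
})

test_that("altloc duplicates keep the first location by default", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C")
  arr <- read_pdb(lines)
  expect_equal(n_atoms(arr), 2L)
  expect_equal(arr$coord[1, 1], 1.000)
  all_alt <- read_pdb(lines, keep_altloc = TRUE)
  expect_equal(n_atoms(all_alt), 3L)
  expect_identical(all_alt$altloc, c("A", "B", " "))
})

test_that("blank element columns are inferred from the atom name", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00"
  arr <- read_pdb(line)
  expect_identical(arr$element, "C")
  # two-letter element, left-justified name column
  line2 <- "HETATM    1 FE   HEM A   1       1.000   2.000   3.000  1.00  0.00"
  expect_identical(read_pdb(line2)$element, "FE")
})

test_that("mmCIF loop and key-value categories parse to equal-length columns", {
  cif <- c(
    "data_test",
    "_cell.length_a 78.9",
    "_cell.length_b '10.2'",
    "_struct.title",
    ";a title",
    "spanning lines",
    ";",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.type_symbol",
    "ATOM 1 N ALA A 1 11.104 6.134 -6.504 N",
    "ATOM 2 CA ALA A 1 11.639 6.071 -5.147 C",
    "ATOM 3 C ALA A 1 12.500 7.200 -4.600 C",
    "ATOM 4 'O 1' ALA A 1 13.000 8.000 -4.000 O",
    "HETATM 5 O HOH A 2 9.000 1.000 2.500 O")
  tabs <- read_mmcif(cif)
  expect_equal(tabs$cell$length_a, "78.9")
  expect_equal(tabs$cell$length_b, "10.2")
  expect_match(tabs$struct$title, "a title\nspanning lines")
  expect_true(all(lengths(tabs$atom_site) == 5L))
  expect_equal(tabs$atom_site$label_atom_id[4], "O 1")
  arr <- mmcif_to_atoms(tabs)
  expect_equal(n_atoms(arr), 5L)
  expect_identical(arr$hetero, c(rep(FALSE, 4), TRUE))
  expect_equal(arr$coord[1, ], c(11.104, 6.134, -6.504))
})

test_that("mmCIF loops with wrong value counts are rejected", {
  cif <- c("data_x", "loop_", "_a.p", "_a.q", "1 2 3")
  expect_error(read_mmcif(cif), "not divisible")
  cif2 <- c("data_x", "loop_", "_atom_site.id", "1", "2")
  expect_error(mmcif_to_atoms(read_mmcif(cif2)), "mandatory items")
})

test_that("mmCIF write -> read round trip at written precision", {
  arr <- random_structure(60, seed = 41)
  back <- mmcif_to_atoms(read_mmcif(write_mmcif(arr)))
  expect_same_annotations(back, arr)
  expect_coords_equal(back, arr, tol = 5e-4 + 1e-9)
  st <- random_stack(25, 2, seed = 42)
  back2 <- mmcif_to_atoms(read_mmcif(write_mmcif(st)))
  expect_equal(n_models(back2), 2L)
  expect_coords_equal(back2, st, tol = 5e-4 + 1e-9)
})

test_that("format triangle preserves structure at every hop", {
  # PDB -> internal -> MMTF -> internal -> mmCIF -> internal
  st <- random_stack(500 %/% 3, 3, seed = 43)
  st$coord <- round(st$coord, 3)
  tol <- 5e-4 + 1e-9
  pdb_text <- write_pdb(st)
  s1 <- read_pdb(pdb_text)
  expect_same_annotations(s1, st)
  expect_coords_equal(s1, st, tol)
  s2 <- decode_mmtf(encode_mmtf(s1))
  expect_same_annotations(s2, st)
  expect_coords_equal(s2, st, tol)
  s3 <- mmcif_to_atoms(read_mmcif(write_mmcif(s2)))
  expect_same_annotations(s3, st)
  expect_coords_equal(s3, st, tol)
})

test_that("readers are total on their writers' output (fixed point)", {
  arr <- random_structure(40, seed = 44)
  arr$coord <- round(arr$coord, 3)
  p1 <- write_pdb(read_pdb(write_pdb(arr)))
  expect_identical(write_pdb(read_pdb(p1)), p1)
  c1 <- write_mmcif(mmcif_to_atoms(read_mmcif(write_mmcif(arr))))
  expect_identical(write_mmcif(mmcif_to_atoms(read_mmcif(c1))), c1)
  m1 <- encode_mmtf(decode_mmtf(encode_mmtf(arr)))
  expect_identical(encode_mmtf(decode_mmtf(m1)), m1)
})

test_that("file-based structure reading dispatches on extension", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture("toy_structure_files", seed = 45, dir = dir,
                            n = 30)
  a <- read_pdb(paths[["pdb"]])
  b <- mmcif_to_atoms(read_mmcif(paths[["cif"]]))
  c <- read_mmtf(paths[["mmtf"]])
  expect_same_annotations(b, a)
  expect_same_annotations(c, a)
  expect_coords_equal(b, a, 5e-4 + 1e-9)
  expect_coords_equal(c, a, 5e-4 + 1e-9)
})
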