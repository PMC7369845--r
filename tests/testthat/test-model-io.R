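# Structure and table I/O: partitioning, hydrogen-parent linking,
# round-trips, multi-model trajectories, energy-table parsing.

toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       3.230   1.590   0.000  1.00  0.00           O",
  "ATOM      5  N   GLY A   2       1.200   2.440   0.000  1.00  0.00           N",
  "ATOM      6  CA  GLY A   2       1.650   3.820   0.000  1.00  0.00           C",
  "ATOM      7  C   GLY A   2       0.560   4.880   0.000  1.00  0.00           C",
  "ATOM      8  O   GLY A   2      -0.640   4.600   0.000  1.00  0.00           O",
  "ATOM      9  N   SER A   3       0.980   6.140   0.000  1.00  0.00           N",
  "ATOM     10  CA  SER A   3       0.050   7.270   0.000  1.00  0.00           C",
  "ATOM     11  OG  SER A   3       0.750   8.510   0.000  1.00  0.00           O",
  "HETATM   12  C1  LIG B   9       6.000   1.000   0.000  1.00  0.00           C",
  "HETATM   13  N1  LIG B   9       7.350   1.000   0.000  1.00  0.00           N",
  "HETATM   14  H1  LIG B   9       8.360   1.000   0.000  1.00  0.00           H",
  "HETATM   15  O   HOH W 101       5.000   5.000   0.000  1.00  0.00           O",
  "END")

test_that("complex reading partitions protein/ligand/water and links hydrogens", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines, f)
  cx <- read_complex(f, "LIG")
  at <- cx$atoms
  expect_equal(nrow(at), 15)  # no record silently dropped
  expect_equal(length(unique(at$residue_key[at$moiety == "protein"])), 3)
  expect_equal(sum(at$moiety == "ligand"), 3)
  expect_equal(sum(at$moiety == "water"), 1)
  # hydrogen linked to its N (1.01 A), not the carbon further away
  h <- at[at$elety == "H1", ]
  expect_equal(at$elety[match(h$parent, at$eleno)], "N1")
  # chain:resno selector picks the same residue
  cx2 <- read_complex(f, "B:9")
  expect_equal(cx2$atoms$moiety, cx$atoms$moiety)
})

test_that("ligand selection errors: no match and ambiguous match", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines, f)
  expect_error(read_complex(f, "XYZ"), "matches no residue")
  dup <- c(toy_pdb_lines[1:15],
           "HETATM   16  C1  LIG C   9       9.000   9.000   0.000  1.00  0.00           C",
           "END")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(dup, f2)
  expect_error(read_complex(f2, "LIG"), "ambiguous")
})

test_that("a hydrogen with no heavy atom within 1.2 A is a topology error", {
  bad <- c(toy_pdb_lines[1:14],
           "HETATM   16  H9  LIG B   9      12.000  12.000   0.000  1.00  0.00           H",
           "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f)
  expect_error(read_complex(f, "LIG"), "no heavy atom within 1.2")
})

test_that("complex write -> read round-trips atoms, coordinates and charges", {
  sc <- build_pocket(six_kind_specs(), n_decoy_residues = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(sc$complex, f)
  cx2 <- read_complex(f, "LIG")
  expect_equal(nrow(cx2$atoms), nrow(sc$complex$atoms))
  expect_equal(cx2$atoms$elety, sc$complex$atoms$elety)
  expect_equal(cx2$atoms$residue_key, sc$complex$atoms$residue_key)
  # bit-exact to the writer's 3-decimal precision
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               round(as.matrix(sc$complex$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
  expect_equal(cx2$atoms$formal_charge, sc$complex$atoms$formal_charge)
})

test_that("trajectory reading: frame counts, times, REMARK TIME, mismatch error", {
  sc <- build_pocket(list(plant_spec("hbond")), n_decoy_residues = 2, seed = 2)
  tr <- build_trajectory(sc, n_frames = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, sc$complex)
  expect_equal(nrow(tr2$xyz), 5)
  expect_equal(tr2$times, 0:4 + 0)
  expect_equal(tr2$xyz, round(tr$xyz, 3), tolerance = 1e-9, ignore_attr = TRUE)
  # 1-model file
  tr1 <- build_trajectory(sc, n_frames = 1, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr1, f1)
  got1 <- read_trajectory(f1, sc$complex)
  expect_equal(nrow(got1$xyz), 1)
  expect_equal(got1$times, 0)
  # custom REMARK TIME values survive
  tr$times <- c(0, 2.5, 5, 7.5, 10)
  write_trajectory(tr, f)
  expect_equal(read_trajectory(f, sc$complex)$times, tr$times)
  # atom-count mismatch names the model
  lines <- readLines(f)
  first_atom <- grep("^ATOM", lines)[1]
  writeLines(lines[-first_atom], f)
  expect_error(read_trajectory(f, sc$complex), "model 1")
})

test_that("energy tables parse, allow absent totals, and reject junk", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\tresidue\te_elst\te_exch\te_ind\te_disp",
               "8\tALA866\t-5.32\t5.67\t-1.48\t-5.14"), f)
  tab <- read_energy_table(f, "sapt")
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$e_total))
  expect_equal(sapt_total(tab), -6.27)
  # header-only file -> empty collection
  writeLines("ligand\tresidue\te_elst\te_exch\te_ind\te_disp", f)
  expect_equal(nrow(read_energy_table(f, "sapt")), 0)
  # non-numeric component -> parse error naming the row
  writeLines(c("ligand\tresidue\te_elst\te_exch\te_ind\te_disp",
               "8\tALA866\t-5.32\t5.67\t-1.48\t-5.14",
               "9\tCYS919\tabc\t1\t1\t1"), f)
  expect_error(read_energy_table(f, "sapt"), "row 2")
  # unknown schema -> usage error
  expect_error(read_energy_table(f, "mmpbsa"), "arg")
})

test_that("energy tables round-trip through TSV", {
  et <- build_energy_tables(2, 5, 0, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  for (schema in c("sapt", "pieda", "enthalpy")) {
    write_energy_table(et[[schema]], f, schema)
    back <- read_energy_table(f, schema)
    for (cn in setdiff(names(back), c("ligand", "residue")))
      expect_equal(back[[cn]], et[[schema]][[cn]], tolerance = 1e-9)
  }
})
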