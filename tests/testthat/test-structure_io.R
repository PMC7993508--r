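# Reading, cleaning and filtering of protein/ligand structures.

minimal_pdb <- function(path, with_water = TRUE) {
  lines <- c(
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ARG A  45      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ARG A  45      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  N   GLY A  46       9.500   5.000  -4.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A  46      10.000   4.800  -2.700  1.00  0.00           C",
    if (with_water)
      "HETATM    5  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

test_that("water removal drops HOH but keeps standard residues and coordinates", {
  path <- minimal_pdb(tempfile(fileext = ".pdb"))
  prot <- read_protein(path)
  expect_true(prot$waters_removed)
  expect_false(any(prot$atoms$resid %in% plifr:::WATER_RESIDUES))
  expect_setequal(unique(prot$atoms$resid), c("ARG", "GLY"))
  expect_equal(length(plifr:::residue_index(prot$atoms)), 2)
  expect_equal(prot$resolution, 1.8)
  # coordinates of retained atoms are untouched by the water filter
  kept <- read_protein(path, remove_waters = FALSE)
  std <- kept$atoms[kept$atoms$resid != "HOH", c("x", "y", "z")]
  expect_equal(unname(as.matrix(std)),
               unname(as.matrix(prot$atoms[, c("x", "y", "z")])))
})

test_that("a PDB with no standard residues is an empty-structure error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_protein(path), "no standard amino-acid residues")
  expect_error(read_protein(tempfile(fileext = ".pdb")), "not found")
})

test_that("donor hydrogen placement adds H on donors and flags the structure", {
  spec <- plant_spec(data.frame(residue_name = "SER",
                                interaction_class = "HBOND_ACC_LIG",
                                distance = 3.0))
  dir <- tempfile(); toy <- make_toy_complex(spec, dir = dir, id = "h")
  prot <- read_protein(file.path(dir, "h.pdb"), add_hydrogens = TRUE)
  expect_true(prot$hydrogens_present)
  expect_true(any(prot$atoms$element == "H"))
  # hydrogens sit ~1.0 A from their donor
  h <- prot$atoms[prot$atoms$element == "H", ][1, ]
  og <- prot$atoms[prot$atoms$elety == "OG", ]
  expect_equal(sqrt((h$x - og$x)^2 + (h$y - og$y)^2 + (h$z - og$z)^2), 1.0,
               tolerance = 1e-6)
})

test_that("written structures round-trip atoms, residues and coordinates", {
  toy <- make_toy_complex(random_plant_spec(3), dir = tempfile(), id = "rt")
  prot <- read_protein(toy$paths["protein"])
  lig <- read_ligand(toy$paths["ligand"])
  expect_equal(nrow(prot$atoms), nrow(toy$protein$atoms))
  expect_equal(length(plifr:::residue_index(prot$atoms)),
               length(plifr:::residue_index(toy$protein$atoms)))
  expect_equal(as.matrix(prot$atoms[, c("x", "y", "z")]),
               as.matrix(toy$protein$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(nrow(lig$atoms), nrow(toy$ligand$atoms))
  expect_equal(as.matrix(lig$atoms[, c("x", "y", "z")]),
               as.matrix(toy$ligand$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(lig$atoms$charge, toy$ligand$atoms$charge)
})

test_that("SDF reading perceives known molecules", {
  bz <- tempfile(fileext = ".sdf")
  write_test_sdf(benzene_mol(), bz)
  mol <- read_ligand(bz)
  expect_equal(nrow(mol$atoms), 6)
  expect_true(all(mol$atoms$aromatic))
  expect_true(all(mol$bonds$aromatic))
  # Kekule input (alternating 1/2 orders) is perceived as aromatic too
  kz <- tempfile(fileext = ".sdf")
  write_test_sdf(benzene_mol(), kz, kekule_orders = c(1, 2, 1, 2, 1, 2))
  expect_true(all(read_ligand(kz)$atoms$aromatic))

  et <- tempfile(fileext = ".sdf")
  write_test_sdf(ethanol_mol(), et)
  mol <- read_ligand(et)
  expect_equal(mol$atoms$element, c("C", "C", "O"))
  expect_equal(nrow(mol$bonds), 2)

  ac <- tempfile(fileext = ".sdf")
  write_test_sdf(acetate_mol(), ac)
  expect_equal(sum(read_ligand(ac)$atoms$charge), -1)
})

test_that("acetate MOL2 with an explicit formal charge carries net charge -1", {
  path <- tempfile(fileext = ".mol2")
  write_ligand_mol2(acetate_mol(), path)
  mol <- read_ligand(path)
  expect_equal(sum(mol$atoms$charge), -1)
})

test_that("disconnected ligands are reduced to the largest fragment with a warning", {
  frag <- make_ligand(c("C", "C", "C", "O"),
                      data.frame(i = c(1, 2), j = c(2, 3), order = 1,
                                 aromatic = FALSE))
  path <- tempfile(fileext = ".mol2")
  write_ligand_mol2(frag, path)
  expect_warning(mol <- read_ligand(path), "disconnected")
  expect_equal(nrow(mol$atoms), 3)
  expect_equal(sort(mol$atoms$element), c("C", "C", "C"))
})

test_that("resolution filter is strict and drops IC50 and unresolved entries", {
  recs <- data.frame(
    id = c("a", "b", "c", "d"),
    resolution = c(2.4, 2.5, 2.0, NA),
    affinity_type = c("Kd", "Kd", "IC50", "Ki"),
    stringsAsFactors = FALSE)
  out <- filter_complexes(recs)
  expect_equal(out$id, "a")
  # NMR-style entries pass only under the explicit flag
  out2 <- filter_complexes(recs, allow_missing_resolution = TRUE)
  expect_equal(out2$id, c("a", "d"))
  # idempotent; empty in -> empty out; order preserved
  expect_identical(filter_complexes(out), out)
  expect_equal(nrow(filter_complexes(recs[0, , drop = FALSE])), 0)
})

test_that("filter_complexes also works on lists of complex records", {
  recs <- list(
    structure(list(id = "x", resolution = 1.9, affinity_type = "Ki"),
              class = "complex_record"),
    structure(list(id = "y", resolution = 3.0, affinity_type = "Ki"),
              class = "complex_record"))
  out <- filter_complexes(recs)
  expect_length(out, 1)
  expect_equal(out[[1]]$id, "x")
})
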