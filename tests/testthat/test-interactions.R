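# Geometric interaction detection and the fingerprint/distance folds.

planted_one <- function(resname, class, distance) {
  make_toy_complex(plant_spec(data.frame(
    residue_name = resname, interaction_class = class, distance = distance)))
}

test_that("each interaction class is detected exactly as planted", {
  cases <- data.frame(
    residue_name = c("ALA", "PHE", "TYR", "SER", "GLY", "ARG", "ASP"),
    interaction_class = c("HYDROPHOBIC", "AR_F2F", "AR_E2F", "HBOND_ACC_LIG",
                          "HBOND_DON_LIG", "IONIC_LIG_NEG", "IONIC_LIG_POS"),
    distance = c(4.0, 3.6, 5.0, 3.0, 3.0, 3.0, 3.0),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    toy <- planted_one(cases$residue_name[k], cases$interaction_class[k],
                       cases$distance[k])
    recs <- detect_interactions(toy$protein, toy$ligand)
    expect_equal(nrow(recs), 1, info = cases$interaction_class[k])
    expect_equal(recs$interaction_class, cases$interaction_class[k])
    expect_equal(recs$residue_name, cases$residue_name[k])
    expect_equal(recs$distance, cases$distance[k], tolerance = 1e-6)
  }
})

test_that("an acetate-like anion 3 A from the arginine guanidinium gives one ionic record", {
  toy <- planted_one("ARG", "IONIC_LIG_NEG", 3.0)
  recs <- detect_interactions(toy$protein, toy$ligand)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$interaction_class, "IONIC_LIG_NEG")
  expect_equal(recs$distance, 3.0, tolerance = 1e-6)
})

test_that("a ligand far beyond every cutoff yields no interactions", {
  toy <- planted_one("ALA", "HYDROPHOBIC", 4.0)
  lig <- toy$ligand
  lig$atoms$x <- lig$atoms$x + 50
  recs <- detect_interactions(toy$protein, lig)
  expect_equal(nrow(recs), 0)
  expect_true(all(build_ifp(recs) == 0))
  expect_true(all(build_intdist(recs) == 0))
})

test_that("fingerprint cells count distinct residues and sum to the record count", {
  toy <- make_toy_complex(plant_spec(data.frame(
    residue_name = c("ARG", "ARG", "SER"),
    interaction_class = c("HBOND_ACC_LIG", "HBOND_ACC_LIG", "HBOND_ACC_LIG"),
    distance = c(2.9, 3.2, 3.0))))
  recs <- detect_interactions(toy$protein, toy$ligand)
  ifp <- build_ifp(recs)
  expect_equal(unname(ifp["ARG_HBOND_ACC_LIG"]), 2L)
  expect_equal(unname(ifp["SER_HBOND_ACC_LIG"]), 1L)
  expect_equal(sum(ifp), nrow(recs))
  # distance fold takes the minimum over the cell
  dist <- build_intdist(recs)
  expect_equal(unname(dist["ARG_HBOND_ACC_LIG_dist"]), 2.9, tolerance = 1e-6)
})

test_that("distance vector is positive exactly where the count is positive", {
  for (s in c(2, 9, 17)) {
    toy <- make_toy_complex(random_plant_spec(s))
    recs <- detect_interactions(toy$protein, toy$ligand)
    ifp <- build_ifp(recs)
    dist <- build_intdist(recs)
    expect_identical(unname(dist > 0), unname(ifp > 0))
    expect_equal(sum(ifp), nrow(recs))
  }
})

test_that("records with non-standard residues are skipped with a warning", {
  recs <- data.frame(residue_name = c("ARG", "XYZ"), chain = "A",
                     resno = 1:2, interaction_class = "HYDROPHOBIC",
                     distance = c(4.0, 4.0), stringsAsFactors = FALSE)
  expect_warning(ifp <- build_ifp(recs), "XYZ")
  expect_equal(sum(ifp), 1)
})

test_that("fingerprints are invariant to atom and residue input ordering", {
  toy <- make_toy_complex(random_plant_spec(21, max_plants = 5))
  ref <- build_ifp(detect_interactions(toy$protein, toy$ligand))
  for (s in 1:5) {
    lig <- shuffle_ligand(toy$ligand, seed = s)
    prot <- toy$protein
    set.seed(s)
    perm <- sample.int(nrow(prot$atoms))
    prot$atoms <- prot$atoms[perm, , drop = FALSE]
    rownames(prot$atoms) <- NULL
    expect_identical(build_ifp(detect_interactions(prot, lig)), ref)
  }
})

test_that("rigid rotation plus translation leaves fingerprint and distances unchanged", {
  toy <- make_toy_complex(random_plant_spec(33, max_plants = 5))
  recs0 <- detect_interactions(toy$protein, toy$ligand)
  for (s in 1:3) {
    moved <- rigid_transform_complex(toy$protein, toy$ligand, seed = s)
    recs1 <- detect_interactions(moved$protein, moved$ligand)
    expect_identical(build_ifp(recs1), build_ifp(recs0))
    expect_equal(build_intdist(recs1), build_intdist(recs0), tolerance = 1e-6)
  }
})

test_that("shrinking any cutoff never increases any fingerprint cell", {
  toy <- make_toy_complex(random_plant_spec(5, max_plants = 6))
  base <- build_ifp(detect_interactions(toy$protein, toy$ligand))
  shrunk_sets <- list(
    geometric_rules(hydrophobic_cutoff = 3.8),
    geometric_rules(hbond_da_cutoff = 2.8),
    geometric_rules(ionic_cutoff = 3.0),
    geometric_rules(f2f_centroid_cutoff = 3.4, e2f_centroid_cutoff = 4.8),
    geometric_rules(hydrophobic_cutoff = 1.0, hbond_da_cutoff = 1.0,
                    ionic_cutoff = 1.0, f2f_centroid_cutoff = 1.0,
                    e2f_centroid_cutoff = 1.0))
  for (rules in shrunk_sets) {
    shr <- build_ifp(detect_interactions(toy$protein, toy$ligand, rules))
    expect_true(all(shr <= base))
  }
})

test_that("hydrogen-aware detection applies the D-H...A angle criterion", {
  spec <- plant_spec(data.frame(residue_name = "SER",
                                interaction_class = "HBOND_ACC_LIG",
                                distance = 3.0))
  dir <- tempfile()
  make_toy_complex(spec, dir = dir, id = "hb")
  # without hydrogens: distance-only rule fires
  prot <- read_protein(file.path(dir, "hb.pdb"))
  lig <- read_ligand(file.path(dir, "hb.mol2"))
  expect_equal(nrow(detect_interactions(prot, lig)), 1)
  # with placed hydrogens the donor H points at the acceptor (the fixture
  # builds near-linear geometry), so the record survives the angle test
  ph <- read_protein(file.path(dir, "hb.pdb"), add_hydrogens = TRUE)
  recs <- detect_interactions(ph, lig)
  expect_equal(recs$interaction_class, "HBOND_ACC_LIG")

  # hand-built bent geometry: the donor H points away from the acceptor,
  # so the D-H...A angle is ~0 degrees and the bond must be rejected
  bent <- function(with_h) {
    atoms <- data.frame(
      eleno = 1:5,
      elety = c("N", "CA", "C", "O", "HN"),
      element = c("N", "C", "C", "O", "H"),
      resid = "GLY", chain = "A", resno = 1,
      x = c(0, 1.40, 2.10, 2.10, 0),
      y = c(0, 0.30, 1.40, 2.63, 0),
      z = c(0, 0.60, 0.90, 0.90, 1.00),
      featurizable = TRUE, stringsAsFactors = FALSE)
    if (!with_h) atoms <- atoms[atoms$element != "H", ]
    structure(list(atoms = atoms, resolution = NA_real_,
                   waters_removed = TRUE,
                   hydrogens_present = with_h),
              class = "protein_structure")
  }
  # ligand carbonyl oxygen 3 A from the donor N, opposite the hydrogen
  acc <- make_ligand(c("O", "C"),
                     data.frame(i = 1, j = 2, order = 2, aromatic = FALSE),
                     coords = rbind(c(0, 0, -3), c(0, 0, -4.23)))
  no_h <- detect_interactions(bent(FALSE), acc)
  expect_equal(no_h$interaction_class, "HBOND_ACC_LIG")
  with_h <- detect_interactions(bent(TRUE), acc)
  expect_false("HBOND_ACC_LIG" %in% with_h$interaction_class)
})

test_that("interaction profiles are written as readable TSV", {
  toy <- make_toy_complex(random_plant_spec(8))
  recs <- detect_interactions(toy$protein, toy$ligand)
  path <- tempfile(fileext = ".tsv")
  write_interaction_profile(recs, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(recs))
  expect_named(back, c("residue_name", "chain", "resno",
                       "interaction_class", "distance"))
})
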