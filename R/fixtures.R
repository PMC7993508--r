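# Synthetic protein-ligand complexes with planted interactions, and
# synthetic labeled feature datasets.
#
# Geometry: each planted interaction occupies one of the six axis rays from
# the origin (90 degrees apart). The ligand probe group sits 3 A from the
# origin along its ray and the residue's interacting group a further
# `distance` A out, so every cross-plant protein-ligand distance exceeds all
# detection cutoffs by construction. Probe groups are bonded to a central
# scaffold carbon so the ligand graph stays connected. Residue templates use
# idealized internal coordinates (no rotamer library): the interacting group
# sits at the local origin and the rest of the residue extends along +z,
# i.e. away from the ligand after placement.

# residue templates: matrix columns elety/element/x/y/z; anchor is row 1
# (or the ring centroid at the local origin for aromatic templates)
res_template <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(elety = r[[1]], element = r[[2]], x = as.numeric(r[[3]]),
               y = as.numeric(r[[4]]), z = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
  df
}

RESIDUE_TEMPLATES <- list(
  ALA = res_template(
    list("CB", "C", 0, 0, 0), list("CA", "C", 0, 0, 1.52),
    list("N", "N", 1.30, 0, 2.20), list("C", "C", -1.20, 0.60, 2.10),
    list("O", "O", -1.30, 1.50, 2.90)),
  LEU = res_template(
    list("CD1", "C", 0, 0, 0), list("CG", "C", 0, 0, 1.53),
    list("CD2", "C", 1.45, 0, 1.95), list("CB", "C", -0.75, 1.20, 2.10),
    list("CA", "C", -0.40, 1.40, 3.55), list("N", "N", 0.95, 1.70, 4.05),
    list("C", "C", -1.35, 2.45, 4.05), list("O", "O", -1.20, 3.60, 4.45)),
  VAL = res_template(
    list("CG1", "C", 0, 0, 0), list("CB", "C", 0, 0, 1.54),
    list("CG2", "C", 1.45, 0, 2.00), list("CA", "C", -0.80, 1.20, 2.05),
    list("N", "N", 0.05, 2.35, 2.50), list("C", "C", -1.60, 1.00, 3.30),
    list("O", "O", -2.75, 1.45, 3.20)),
  PHE = res_template(
    list("CG", "C", 1.394, 0, 0), list("CD1", "C", 0.697, 1.207, 0),
    list("CE1", "C", -0.697, 1.207, 0), list("CZ", "C", -1.394, 0, 0),
    list("CE2", "C", -0.697, -1.207, 0), list("CD2", "C", 0.697, -1.207, 0),
    list("CB", "C", 2.85, 0, 0.55), list("CA", "C", 3.60, 0.55, 1.75),
    list("N", "N", 4.95, 1.05, 1.45), list("C", "C", 3.75, -0.50, 2.90),
    list("O", "O", 4.20, -0.10, 3.95)),
  TYR = res_template(
    list("CG", "C", 1.394, 0, 0), list("CD1", "C", 0.697, 1.207, 0),
    list("CE1", "C", -0.697, 1.207, 0), list("CZ", "C", -1.394, 0, 0),
    list("CE2", "C", -0.697, -1.207, 0), list("CD2", "C", 0.697, -1.207, 0),
    list("OH", "O", -2.76, 0, 0.30), list("CB", "C", 2.85, 0, 0.55),
    list("CA", "C", 3.60, 0.55, 1.75), list("N", "N", 4.95, 1.05, 1.45),
    list("C", "C", 3.75, -0.50, 2.90), list("O", "O", 4.20, -0.10, 3.95)),
  SER = res_template(
    list("OG", "O", 0, 0, 0), list("CB", "C", 0, 0, 1.42),
    list("CA", "C", 1.15, 0.55, 2.20), list("N", "N", 2.40, 0.05, 1.75),
    list("C", "C", 1.10, 0.35, 3.70), list("O", "O", 2.00, 1.00, 4.40)),
  THR = res_template(
    list("OG1", "O", 0, 0, 0), list("CB", "C", 0, 0, 1.43),
    list("CG2", "C", 1.45, 0, 1.90), list("CA", "C", -0.85, 1.15, 2.00),
    list("N", "N", -0.10, 2.35, 2.40), list("C", "C", -1.80, 0.95, 3.25),
    list("O", "O", -2.95, 1.40, 3.15)),
  GLN = res_template(
    list("NE2", "N", 0, 0, 0), list("CD", "C", 0, 0, 1.33),
    list("OE1", "O", 1.10, 0, 2.05), list("CG", "C", -1.25, 0.45, 1.95),
    list("CB", "C", -1.20, 0.65, 3.45), list("CA", "C", -2.45, 1.20, 4.10),
    list("N", "N", -3.55, 0.30, 4.00), list("C", "C", -2.30, 1.55, 5.55),
    list("O", "O", -3.30, 1.90, 6.20)),
  GLN_ACC = res_template(
    list("OE1", "O", 0, 0, 0), list("CD", "C", 0, 0, 1.23),
    list("NE2", "N", 1.12, 0, 1.98), list("CG", "C", -1.25, 0.45, 1.90),
    list("CB", "C", -1.20, 0.65, 3.40), list("CA", "C", -2.45, 1.20, 4.05),
    list("N", "N", -3.55, 0.30, 3.95), list("C", "C", -2.30, 1.55, 5.50),
    list("O", "O", -3.30, 1.90, 6.15)),
  ASN = res_template(
    list("ND2", "N", 0, 0, 0), list("CG", "C", 0, 0, 1.33),
    list("OD1", "O", 1.10, 0, 2.05), list("CB", "C", -1.25, 0.45, 1.95),
    list("CA", "C", -1.20, 0.65, 3.45), list("N", "N", -2.40, 1.15, 4.15),
    list("C", "C", -0.05, 1.45, 4.15), list("O", "O", 0.95, 0.95, 4.75)),
  ASN_ACC = res_template(
    list("OD1", "O", 0, 0, 0), list("CG", "C", 0, 0, 1.23),
    list("ND2", "N", 1.12, 0, 1.98), list("CB", "C", -1.25, 0.45, 1.90),
    list("CA", "C", -1.20, 0.60, 3.40), list("N", "N", -2.35, 1.20, 4.05),
    list("C", "C", 0.00, 1.45, 4.10), list("O", "O", 1.00, 1.00, 4.70)),
  GLY = res_template(
    list("O", "O", 0, 0, 0), list("C", "C", 0, 0, 1.23),
    list("CA", "C", 1.20, 0.45, 2.00), list("N", "N", 2.45, -0.10, 1.60)),
  ARG = res_template(
    list("NH1", "N", 0, 0, 0), list("CZ", "C", 0.62, 0, 1.17),
    list("NH2", "N", 2.00, 0, 1.25), list("NE", "N", 0.30, 0, 2.48),
    list("CD", "C", 1.35, 0, 3.35), list("CG", "C", 1.15, 0, 4.85),
    list("CB", "C", 2.30, 0.55, 5.60), list("CA", "C", 2.10, 0.70, 7.10),
    list("N", "N", 3.20, 1.30, 7.80), list("C", "C", 0.85, 1.50, 7.50),
    list("O", "O", 0.90, 2.70, 7.80)),
  ARG_HB = res_template(
    list("N", "N", 0, 0, 0), list("CA", "C", 0, 0, 1.46),
    list("CB", "C", 1.25, 0.50, 2.20), list("C", "C", -1.20, 0.55, 2.10),
    list("O", "O", -1.30, 1.70, 2.60), list("CG", "C", 1.20, 0.60, 3.70),
    list("CD", "C", 2.40, 1.20, 4.40), list("NE", "N", 2.30, 1.20, 5.85),
    list("CZ", "C", 3.40, 1.50, 6.60), list("NH1", "N", 4.60, 1.90, 6.10),
    list("NH2", "N", 3.30, 1.40, 7.95)),
  LYS = res_template(
    list("NZ", "N", 0, 0, 0), list("CE", "C", 0, 0, 1.49),
    list("CD", "C", 1.20, 0.60, 2.20), list("CG", "C", 1.20, 0.60, 3.70),
    list("CB", "C", 2.40, 1.20, 4.40), list("CA", "C", 2.40, 1.20, 5.90),
    list("N", "N", 3.60, 1.80, 6.50), list("C", "C", 1.20, 1.80, 6.60),
    list("O", "O", 1.20, 3.00, 6.90)),
  ASP = res_template(
    list("OD1", "O", 0, 0, 0), list("CG", "C", 0.65, 0, 1.15),
    list("OD2", "O", 1.95, 0, 1.35), list("CB", "C", -0.10, 0.70, 2.20),
    list("CA", "C", 0.60, 0.80, 3.50), list("N", "N", 1.75, 1.65, 3.30),
    list("C", "C", -0.35, 1.30, 4.55), list("O", "O", -1.55, 1.20, 4.40)),
  GLU = res_template(
    list("OE1", "O", 0, 0, 0), list("CD", "C", 0.65, 0, 1.15),
    list("OE2", "O", 1.95, 0, 1.35), list("CG", "C", -0.10, 0.70, 2.20),
    list("CB", "C", 0.60, 0.80, 3.50), list("CA", "C", -0.15, 1.60, 4.55),
    list("N", "N", -1.45, 2.00, 4.20), list("C", "C", 0.60, 2.80, 5.10),
    list("O", "O", 1.70, 3.10, 4.70))
)

# which residue templates can realize each class, the ligand probe used, and
# the distance window (below the default class cutoff)
PLANT_TABLE <- list(
  HYDROPHOBIC = list(residues = c(ALA = "ALA", LEU = "LEU", VAL = "VAL"),
                     probe = "ethane", d_range = c(3.4, 4.4)),
  AR_F2F = list(residues = c(PHE = "PHE", TYR = "TYR"),
                probe = "benzene", d_range = c(3.3, 3.9)),
  AR_E2F = list(residues = c(PHE = "PHE", TYR = "TYR"),
                probe = "benzene", d_range = c(4.6, 5.4)),
  HBOND_ACC_LIG = list(
    residues = c(SER = "SER", THR = "THR", GLN = "GLN", ASN = "ASN",
                 ARG = "ARG_HB"),
    probe = "carbonyl", d_range = c(2.7, 3.4)),
  HBOND_DON_LIG = list(
    residues = c(GLN = "GLN_ACC", ASN = "ASN_ACC", GLY = "GLY"),
    probe = "hydroxyl", d_range = c(2.7, 3.4)),
  IONIC_LIG_NEG = list(residues = c(ARG = "ARG", LYS = "LYS"),
                       probe = "carboxylate", d_range = c(2.8, 3.9)),
  IONIC_LIG_POS = list(residues = c(ASP = "ASP", GLU = "GLU"),
                       probe = "ammonium", d_range = c(2.8, 3.9))
)

# ligand probe groups in local coordinates: contact point at the origin,
# group extending toward the molecule centre along -z; `link` is the atom
# bonded to the central scaffold carbon
ligand_probes <- function() {
  benz <- t(sapply(0:5, function(k) {
    a <- k * pi / 3
    c(1.394 * cos(a), 1.394 * sin(a), 0)
  }))
  list(
    ethane = list(
      atoms = data.frame(element = c("C", "C"),
                         x = c(0, 0), y = c(0, 0), z = c(0, -1.53),
                         charge = 0, aromatic = FALSE),
      bonds = data.frame(i = 1, j = 2, order = 1, aromatic = FALSE),
      link = 2),
    benzene = list(
      atoms = data.frame(element = "C", x = benz[, 1], y = benz[, 2],
                         z = benz[, 3], charge = 0, aromatic = TRUE),
      bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 1, aromatic = TRUE),
      link = 1),
    carbonyl = list(
      atoms = data.frame(element = c("O", "C"),
                         x = c(0, 0), y = c(0, 0), z = c(0, -1.23),
                         charge = 0, aromatic = FALSE),
      bonds = data.frame(i = 1, j = 2, order = 2, aromatic = FALSE),
      link = 2),
    hydroxyl = list(
      atoms = data.frame(element = c("O", "C"),
                         x = c(0, 0), y = c(0, 0), z = c(0, -1.43),
                         charge = 0, aromatic = FALSE),
      bonds = data.frame(i = 1, j = 2, order = 1, aromatic = FALSE),
      link = 2),
    carboxylate = list(
      atoms = data.frame(element = c("O", "C", "O"),
                         x = c(0, 0, 1.10), y = c(0, 0, 0),
                         z = c(0, -1.25, -1.90),
                         charge = c(-1, 0, 0), aromatic = FALSE),
      bonds = data.frame(i = c(2, 2), j = c(1, 3), order = c(1, 2),
                         aromatic = FALSE),
      link = 2),
    ammonium = list(
      atoms = data.frame(element = c("N", "C"),
                         x = c(0, 0), y = c(0, 0), z = c(0, -1.50),
                         charge = c(1, 0), aromatic = FALSE),
      bonds = data.frame(i = 1, j = 2, order = 1, aromatic = FALSE),
      link = 2)
  )
}

# rotation taking the local +z axis onto the unit vector u
frame_rotation <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v1 <- unit(c(a[2] * u[3] - a[3] * u[2],
               a[3] * u[1] - a[1] * u[3],
               a[1] * u[2] - a[2] * u[1]))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  cbind(v1, v2, u)
}

AXIS_RAYS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Specify a planted synthetic complex
#'
#' @param planted Data frame (or list coercible to one) with columns
#'   `residue_name`, `interaction_class`, `distance` (A). At most 6 plants
#'   per complex; the distance must sit in the class's plantable window
#'   (inside the default detection cutoff) and the residue must support the
#'   class (e.g. no PHE ionic contact).
#' @param decoys Number of additional residues placed beyond every cutoff.
#' @param seed Seed used for decoy placement.
#' @return A validated `plant_spec`.
#' @export
plant_spec <- function(planted = NULL, decoys = 0, seed = 1) {
  if (is.null(planted)) {
    planted <- data.frame(residue_name = character(0),
                          interaction_class = character(0),
                          distance = numeric(0))
  }
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (nrow(planted) > nrow(AXIS_RAYS)) {
    stop("at most ", nrow(AXIS_RAYS), " interactions can be planted per complex")
  }
  for (k in seq_len(nrow(planted))) {
    cls <- planted$interaction_class[k]
    entry <- PLANT_TABLE[[cls]]
    if (is.null(entry)) stop("unknown interaction class: ", cls)
    if (!(planted$residue_name[k] %in% names(entry$residues))) {
      stop(planted$residue_name[k], " cannot realize ", cls,
           " (supported: ", paste(names(entry$residues), collapse = ", "), ")")
    }
    d <- planted$distance[k]
    if (d < entry$d_range[1] || d > entry$d_range[2]) {
      stop(cls, " plant distance ", d, " outside the plantable window [",
           entry$d_range[1], ", ", entry$d_range[2], "] A")
    }
  }
  structure(list(planted = planted, decoys = as.integer(decoys),
                 seed = as.integer(seed)), class = "plant_spec")
}

#' Draw a random plantable specification
#'
#' Uniformly samples 1 to `max_plants` interaction classes, compatible
#' residues and in-window distances, plus 0 to `max_decoys` decoy residues.
#'
#' @param seed Integer seed.
#' @param max_plants Maximum planted interactions (<= 6).
#' @param max_decoys Maximum decoy residues.
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(seed, max_plants = 4, max_decoys = 4) {
  with_seed(seed, {
    n <- sample.int(min(max_plants, nrow(AXIS_RAYS)), 1)
    rows <- lapply(seq_len(n), function(k) {
      cls <- sample(names(PLANT_TABLE), 1)
      entry <- PLANT_TABLE[[cls]]
      data.frame(
        residue_name = sample(names(entry$residues), 1),
        interaction_class = cls,
        distance = round(runif(1, entry$d_range[1], entry$d_range[2]), 2),
        stringsAsFactors = FALSE)
    })
    plant_spec(do.call(rbind, rows), decoys = sample(0:max_decoys, 1),
               seed = seed)
  })
}

#' Build a synthetic complex with planted interactions
#'
#' Constructs residues from the internal template library, positions each
#' interacting group at the requested distance with rule-compliant angles,
#' and returns the ground-truth fingerprint implied by the specification
#' (one count per plant in its (residue, class) cell). Decoy residues are
#' placed at least 12 A from the origin, beyond every detection cutoff.
#'
#' @param spec A [plant_spec()].
#' @param dir If non-`NULL`, the complex is also written as `<id>.pdb` and
#'   `<id>.mol2` under this directory (exercising the real readers).
#' @param id Complex identifier used for file names.
#' @return List with `protein` (`protein_structure`), `ligand`
#'   (`ligand_molecule`), `expected_ifp` (named 140 count vector),
#'   `expected_records` (data frame residue/class/distance), and
#'   `paths` (when written).
#' @export
make_toy_complex <- function(spec, dir = NULL, id = "toy") {
  stopifnot(inherits(spec, "plant_spec"))
  probes <- ligand_probes()
  planted <- spec$planted
  n_pl <- nrow(planted)

  prot_rows <- list()
  lig_atoms <- data.frame(element = "C", x = 0, y = 0, z = 0,
                          charge = 0, aromatic = FALSE,
                          stringsAsFactors = FALSE)  # scaffold carbon
  lig_bonds <- data.frame(i = integer(0), j = integer(0),
                          order = numeric(0), aromatic = logical(0))
  resno <- 0

  for (k in seq_len(n_pl)) {
    cls <- planted$interaction_class[k]
    entry <- PLANT_TABLE[[cls]]
    tmpl <- RESIDUE_TEMPLATES[[entry$residues[[planted$residue_name[k]]]]]
    d <- planted$distance[k]
    u <- AXIS_RAYS[k, ]
    R <- frame_rotation(u)

    coords <- as.matrix(tmpl[, c("x", "y", "z")])
    if (cls == "AR_E2F") {
      # stand the residue ring up: 90 degree pre-rotation about local x
      rx <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
      coords <- coords %*% t(rx)
    }
    placed <- coords %*% t(R)
    placed <- sweep(placed, 2, (3 + d) * u, "+")
    resno <- resno + 1
    prot_rows[[length(prot_rows) + 1]] <- data.frame(
      elety = tmpl$elety, element = tmpl$element,
      resid = planted$residue_name[k], chain = "A", resno = resno,
      x = placed[, 1], y = placed[, 2], z = placed[, 3],
      stringsAsFactors = FALSE)

    probe <- probes[[entry$probe]]
    pcoords <- as.matrix(probe$atoms[, c("x", "y", "z")]) %*% t(R)
    pcoords <- sweep(pcoords, 2, 3 * u, "+")
    offset <- nrow(lig_atoms)
    lig_atoms <- rbind(lig_atoms, data.frame(
      element = probe$atoms$element, x = pcoords[, 1], y = pcoords[, 2],
      z = pcoords[, 3], charge = probe$atoms$charge,
      aromatic = probe$atoms$aromatic, stringsAsFactors = FALSE))
    lig_bonds <- rbind(lig_bonds,
      data.frame(i = probe$bonds$i + offset, j = probe$bonds$j + offset,
                 order = probe$bonds$order, aromatic = probe$bonds$aromatic),
      data.frame(i = 1, j = probe$link + offset, order = 1, aromatic = FALSE))
  }

  # decoys: far shell, deterministic directions from the spec seed
  if (spec$decoys > 0) {
    decoy_names <- with_seed(spec$seed, sample(names(RESIDUE_TEMPLATES),
                                               spec$decoys, replace = TRUE))
    dirs <- with_seed(spec$seed + 1, {
      m <- matrix(rnorm(3 * spec$decoys), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    for (k in seq_len(spec$decoys)) {
      tmpl <- RESIDUE_TEMPLATES[[decoy_names[k]]]
      u <- dirs[k, ]
      placed <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(frame_rotation(u))
      placed <- sweep(placed, 2, (12 + 3 * (k - 1)) * u, "+")
      resno <- resno + 1
      prot_rows[[length(prot_rows) + 1]] <- data.frame(
        elety = tmpl$elety, element = tmpl$element,
        resid = sub("_.*$", "", decoy_names[k]), chain = "A", resno = resno,
        x = placed[, 1], y = placed[, 2], z = placed[, 3],
        stringsAsFactors = FALSE)
    }
  }

  if (!length(prot_rows)) stop("a toy complex needs at least one plant or decoy")
  patoms <- do.call(rbind, prot_rows)
  patoms$eleno <- seq_len(nrow(patoms))
  patoms$featurizable <- TRUE
  protein <- structure(
    list(atoms = patoms[, c("eleno", "elety", "element", "resid", "chain",
                            "resno", "x", "y", "z", "featurizable")],
         resolution = 2.0, waters_removed = TRUE, hydrogens_present = FALSE),
    class = "protein_structure")
  ligand <- new_ligand(lig_atoms, lig_bonds, name = id)

  expected_records <- if (n_pl) {
    data.frame(residue_name = planted$residue_name,
               interaction_class = planted$interaction_class,
               distance = planted$distance, stringsAsFactors = FALSE)
  } else {
    data.frame(residue_name = character(0), interaction_class = character(0),
               distance = numeric(0))
  }
  expected_ifp <- build_ifp(
    data.frame(residue_name = expected_records$residue_name,
               interaction_class = expected_records$interaction_class,
               stringsAsFactors = FALSE))

  out <- list(protein = protein, ligand = ligand,
              expected_ifp = expected_ifp,
              expected_records = expected_records, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pp <- file.path(dir, paste0(id, ".pdb"))
    lp <- file.path(dir, paste0(id, ".mol2"))
    write_protein_pdb(protein, pp)
    write_ligand_mol2(ligand, lp)
    out$paths <- c(protein = pp, ligand = lp)
  }
  out
}

#' Generate a synthetic labeled feature dataset
#'
#' Feature rows mimic fingerprint statistics: Poisson(1) counts in the 140
#' count cells and, for the `+dist` layout, uniform 2.5-4.5 A distances
#' wherever the paired count is positive (0 elsewhere). Labels are
#' `features %*% weights` plus Gaussian noise, so
#' `Var(label) = Var(w . features) + sigma^2` by construction. Reproducible
#' by seed.
#'
#' @param n Number of rows (>= 2).
#' @param weights Weight vector over feature cells; if `NULL`,
#'   `n_informative` cells get standard-normal weights (drawn from `seed`).
#' @param sigma Label noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param feature_set `"ifp"` (140 columns) or `"ifp+dist"` (280).
#' @param n_informative Number of non-zero default weights.
#' @return A `labeled_dataset` with the generating `weights` and `sigma`
#'   attached as attributes.
#' @export
make_synthetic_dataset <- function(n, weights = NULL, sigma = 0.1, seed = 1,
                                   feature_set = "ifp", n_informative = 10) {
  stopifnot(n >= 2, sigma >= 0)
  feature_set <- normalize_feature_set(feature_set)
  if (!(feature_set %in% c("ifp", "ifp+dist"))) {
    stop("synthetic datasets support the 'ifp' and 'ifp+dist' layouts")
  }
  p_cnt <- 140
  with_seed(seed, {
    counts <- matrix(rpois(n * p_cnt, 1), n, p_cnt,
                     dimnames = list(NULL, ifp_feature_names()))
    X <- counts
    if (feature_set == "ifp+dist") {
      dist <- matrix(runif(n * p_cnt, 2.5, 4.5), n, p_cnt) * (counts > 0)
      colnames(dist) <- ifp_feature_names(distances = TRUE)
      X <- cbind(counts, dist)
    }
    if (is.null(weights)) {
      weights <- numeric(ncol(X))
      weights[sample.int(ncol(X), n_informative)] <- rnorm(n_informative)
    }
    stopifnot(length(weights) == ncol(X))
    y <- drop(X %*% weights) + rnorm(n, 0, sigma)
    ds <- make_labeled_dataset(sprintf("S%04d", seq_len(n)), X, y, feature_set)
    attr(ds, "weights") <- weights
    attr(ds, "sigma") <- sigma
    ds
  })
}
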