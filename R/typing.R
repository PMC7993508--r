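# Pharmacophoric atom typing for proteins (fixed residue/atom-name table)
# and ligands (element, formal charge, aromaticity, neighbour pattern).
#
# Typing-level exclusivity: atoms belonging to a charged functional group are
# ionic-only -- they are removed from the donor/acceptor lists so that a salt
# bridge is reported once, as an ionic contact, and not a second time as a
# hydrogen bond at the same geometry.

# Side-chain donor/acceptor tables (backbone N/O handled separately).
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = "NE2", SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1"
)
SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = "ND1", SER = "OG", THR = "OG1", TYR = "OH"
)
CATION_GROUPS <- list(
  ARG = list(guanidinium = c("NE", "NH1", "NH2")),
  LYS = list(ammonium = "NZ")
)
ANION_GROUPS <- list(
  ASP = list(carboxylate = c("OD1", "OD2")),
  GLU = list(carboxylate = c("OE1", "OE2"))
)
RESIDUE_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

donor_atom_names <- function(res) {
  base <- if (res == "PRO") character(0) else "N"  # proline has no amide H
  c(base, SIDECHAIN_DONORS[[res]])
}

acceptor_atom_names <- function(res) {
  c("O", "OXT", SIDECHAIN_ACCEPTORS[[res]])
}

#' Assign pharmacophoric atom types
#'
#' Generic over `protein_structure` and `ligand_molecule`. Protein typing
#' comes from a fixed residue/atom-name table (LYS NZ and the ARG guanidinium
#' are cationic, ASP/GLU carboxylates anionic, aromatic rings of
#' PHE/TYR/TRP/HIS, backbone and polar side-chain N/O donors/acceptors, C and
#' S atoms hydrophobic). Ligand typing uses element, formal charge, aromatic
#' flags and the heavy-neighbour pattern. Atoms of charged groups are typed
#' ionic-only (no donor/acceptor role); histidine is treated as aromatic and
#' becomes cationic only when explicitly marked protonated.
#'
#' @param structure A `protein_structure` or `ligand_molecule`.
#' @param ... Method-specific options (e.g. `protonated_his`).
#' @return The input with a `typing` element attached (classes
#'   `typed_protein` / `typed_ligand` added).
#' @export
assign_atom_types <- function(structure, ...) UseMethod("assign_atom_types")

#' @rdname assign_atom_types
#' @param protonated_his Treat histidine as doubly protonated (cationic ring).
#' @export
assign_atom_types.protein_structure <- function(structure,
                                                protonated_his = FALSE, ...) {
  atoms <- structure$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  residues <- list()
  skipped <- character(0)
  for (idx in residue_index(atoms)) {
    res <- atoms$resid[idx[1]]
    if (!(res %in% AA3)) {
      if (!(res %in% WATER_RESIDUES)) skipped <- c(skipped, res)
      next
    }
    name_of <- atoms$elety[idx]
    pick <- function(nms) idx[name_of %in% nms]
    cation <- lapply(CATION_GROUPS[[res]] %||% list(), pick)
    if (protonated_his && res == "HIS") {
      cation <- c(cation, list(imidazolium = pick(c("ND1", "NE2"))))
    }
    anion <- lapply(ANION_GROUPS[[res]] %||% list(), pick)
    if ("OXT" %in% name_of) {
      anion <- c(anion, list(cterm_carboxylate = pick(c("O", "OXT"))))
    }
    cation <- Filter(length, cation)
    anion <- Filter(length, anion)
    charged <- unlist(c(cation, anion), use.names = FALSE)
    donors <- setdiff(pick(donor_atom_names(res)), charged)
    acceptors <- setdiff(pick(acceptor_atom_names(res)), charged)
    if (protonated_his && res == "HIS") acceptors <- setdiff(acceptors, pick("ND1"))
    hydroph <- idx[atoms$element[idx] %in% c("C", "S")]
    rings <- Filter(function(r) length(r) >= 5,
                    lapply(RESIDUE_RINGS[[res]] %||% list(), pick))
    hyd <- idx[atoms$element[idx] == "H"]
    residues[[length(residues) + 1]] <- list(
      resid = res, chain = atoms$chain[idx[1]], resno = atoms$resno[idx[1]],
      atoms = idx, hydrophobic = hydroph, donors = donors,
      acceptors = acceptors, cation_groups = cation, anion_groups = anion,
      rings = rings, hydrogens = hyd
    )
  }
  if (length(skipped)) {
    message("excluded non-standard residues from typing: ",
            paste(unique(skipped), collapse = ", "))
  }
  structure$typing <- list(residues = residues, xyz = xyz)
  class(structure) <- unique(c("typed_protein", class(structure)))
  structure
}

#' @rdname assign_atom_types
#' @export
assign_atom_types.ligand_molecule <- function(structure, ...) {
  mol <- structure
  atoms <- mol$atoms
  n <- nrow(atoms)
  adj <- ligand_adjacency(mol)
  el <- atoms$element
  # total bond order to heavy neighbours (aromatic counted as 1.5)
  bond_order_sum <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k]
    bond_order_sum[mol$bonds$i[k]] <- bond_order_sum[mol$bonds$i[k]] + o
    bond_order_sum[mol$bonds$j[k]] <- bond_order_sum[mol$bonds$j[k]] + o
  }
  degree <- lengths(adj)

  # charged groups: each charged atom seeds a group; a carboxylate-like
  # pattern (O- on a carbon carrying another terminal O) groups both oxygens
  anion_groups <- list()
  cation_groups <- list()
  grouped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (grouped[i] || atoms$charge[i] == 0) next
    grp <- i
    if (atoms$charge[i] < 0 && el[i] == "O") {
      for (c_at in adj[[i]]) {
        if (el[c_at] != "C") next
        twins <- adj[[c_at]][el[adj[[c_at]]] == "O" & degree[adj[[c_at]]] == 1]
        grp <- union(grp, twins)
      }
    }
    grouped[grp] <- TRUE
    if (atoms$charge[i] < 0) anion_groups[[length(anion_groups) + 1]] <- grp
    else cation_groups[[length(cation_groups) + 1]] <- grp
  }
  charged <- which(grouped)

  aromatic <- atoms$aromatic
  # hydrophobic: carbons bonded only to carbons, plus neutral sulfur
  hydrophobic <- which(
    (el == "C" & vapply(seq_len(n), function(i)
      all(el[adj[[i]]] == "C"), logical(1))) |
    (el == "S" & atoms$charge == 0)
  )
  # donors: uncharged O/N that plausibly carry a hydrogen
  is_donor <- (el == "O" & degree == 1 & bond_order_sum <= 1) |
    (el == "N" & !aromatic & bond_order_sum < 3) |
    (el == "N" & aromatic & degree == 3)
  # acceptors: uncharged O; sp3/sp2 N with a lone pair; pyridine-like ring N
  is_acceptor <- (el == "O") |
    (el == "N" & !aromatic & degree <= 2 & bond_order_sum <= 3) |
    (el == "N" & aromatic & degree == 2)
  donors <- setdiff(which(is_donor & atoms$charge == 0), charged)
  acceptors <- setdiff(which(is_acceptor & atoms$charge <= 0), charged)

  rings <- Filter(function(r) all(atoms$aromatic[r]),
                  find_rings(mol, sizes = c(5, 6)))

  mol$typing <- list(
    hydrophobic = hydrophobic, donors = donors, acceptors = acceptors,
    anion_groups = anion_groups, cation_groups = cation_groups,
    rings = rings, xyz = as.matrix(atoms[, c("x", "y", "z")])
  )
  class(mol) <- unique(c("typed_ligand", class(mol)))
  mol
}

ring_centroid <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

# Unit normal of the best plane through the ring atoms (SVD).
ring_normal <- function(xyz, idx) {
  m <- sweep(xyz[idx, , drop = FALSE], 2, ring_centroid(xyz, idx))
  svd(m)$v[, 3]
}
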