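# In-code molecule builders and fixture helpers shared across tests.

make_ligand <- function(el, bonds, aromatic = FALSE, charge = 0,
                        coords = NULL) {
  n <- length(el)
  if (is.null(coords)) coords <- cbind(seq_len(n) * 1.5, 0, 0)
  plifr:::new_ligand(
    data.frame(element = el, x = coords[, 1], y = coords[, 2], z = coords[, 3],
               charge = if (length(charge) == 1) rep(charge, n) else charge,
               aromatic = if (length(aromatic) == 1) rep(aromatic, n) else aromatic,
               stringsAsFactors = FALSE),
    bonds)
}

ethanol_mol <- function() {
  make_ligand(c("C", "C", "O"),
              data.frame(i = c(1, 2), j = c(2, 3), order = 1, aromatic = FALSE))
}

benzene_mol <- function() {
  ang <- (0:5) * pi / 3
  make_ligand(rep("C", 6),
              data.frame(i = 1:6, j = c(2:6, 1), order = 1, aromatic = TRUE),
              aromatic = TRUE,
              coords = cbind(1.394 * cos(ang), 1.394 * sin(ang), 0))
}

acetate_mol <- function() {
  make_ligand(c("C", "C", "O", "O"),
              data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 1, 2),
                         aromatic = FALSE),
              charge = c(0, 0, -1, 0),
              coords = rbind(c(0, 0, 0), c(1.5, 0, 0),
                             c(2.1, 1.05, 0), c(2.1, -1.05, 0)))
}

# random connected molecular graph (tree plus extra edges), <= max_atoms heavy
# atoms, mixed elements and bond orders; used by the fragment oracle tests
random_graph_mol <- function(seed, max_atoms = 30) {
  set.seed(seed)
  n <- sample(2:max_atoms, 1)
  parent <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
  bonds <- data.frame(i = parent, j = 2:n,
                      order = sample(1:2, n - 1, replace = TRUE),
                      aromatic = FALSE)
  extra <- sample(0:2, 1)
  for (k in seq_len(extra)) {
    pair <- sort(sample.int(n, 2))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (!(paste(pair[1], pair[2]) %in% key)) {
      bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2],
                                       order = sample(1:2, 1),
                                       aromatic = FALSE))
    }
  }
  make_ligand(sample(c("C", "C", "C", "N", "O", "S"), n, replace = TRUE), bonds)
}

# permute ligand atom numbering (remapping bonds); counts must not change
shuffle_ligand <- function(mol, seed) {
  set.seed(seed)
  n <- nrow(mol$atoms)
  perm <- sample.int(n)            # perm[old] = new index
  atoms <- mol$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- perm[bonds$i]
  bonds$j <- perm[bonds$j]
  plifr:::new_ligand(atoms, bonds[sample.int(nrow(bonds)), , drop = FALSE],
                     mol$name)
}

# rigid rotation + translation applied to protein and ligand together
rigid_transform_complex <- function(protein, ligand, seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + tr[1]
    df$y <- xyz[, 2] + tr[2]
    df$z <- xyz[, 3] + tr[3]
    df
  }
  protein$atoms <- move(protein$atoms)
  protein$typing <- NULL
  class(protein) <- "protein_structure"
  ligand$atoms <- move(ligand$atoms)
  ligand$typing <- NULL
  class(ligand) <- "ligand_molecule"
  list(protein = protein, ligand = ligand)
}

# write a minimal SDF (V2000) from a ligand object, for reader tests
write_test_sdf <- function(mol, path, kekule_orders = NULL) {
  a <- mol$atoms
  b <- mol$bonds
  orders <- if (is.null(kekule_orders)) ifelse(b$aromatic, 4, b$order)
            else kekule_orders
  lines <- c(mol$name, "  plifr-test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element),
             sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, orders))
  chg <- which(a$charge != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                                    collapse = "")))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  path
}

toy_index_dir <- function(n = 6, seed = 11, dir = tempfile("toyidx")) {
  dir.create(dir)
  rows <- lapply(seq_len(n), function(k) {
    spec <- random_plant_spec(seed = seed * 100 + k)
    id <- sprintf("c%02d", k)
    toy <- make_toy_complex(spec, dir = dir, id = id)
    data.frame(id = id, protein_path = paste0(id, ".pdb"),
               ligand_path = paste0(id, ".mol2"),
               affinity = 2 + 0.5 * sum(toy$expected_ifp),
               affinity_type = "Kd", resolution = 2.0,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "index.csv"),
            row.names = FALSE)
  dir
}
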