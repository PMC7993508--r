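# Reading, cleaning and writing protein and ligand structures.

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via [bio3d::read.pdb()]), optionally strips water
#' residues and places polar hydrogens on donor heavy atoms. Non-standard
#' residues are retained but flagged as non-featurizable; fingerprinting only
#' considers the 20 standard amino acids.
#'
#' @param path Path to a PDB file.
#' @param add_hydrogens Place a geometric hydrogen (1.0 A, pointing away from
#'   the mean of the bonded heavy neighbours) on every donor N/O that lacks
#'   one. Only donors get hydrogens; they are used for the D-H...A angle test
#'   in hydrogen-bond detection. Default `FALSE` (distance-only H-bond rule).
#' @param remove_waters Drop HOH/WAT-type residues. Default `TRUE`.
#' @return A `protein_structure`: list with `atoms` (data.frame: `eleno`,
#'   `elety`, `element`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#'   `featurizable`), `resolution` (A, `NA` if absent from the header),
#'   `waters_removed`, `hydrogens_present`.
#' @export
read_protein <- function(path, add_hydrogens = FALSE, remove_waters = TRUE) {
  if (!file.exists(path)) stop("protein file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  # drop alternate locations beyond the first
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("A", "1"), ]
  atoms <- data.frame(
    eleno = at$eleno,
    elety = at$elety,
    element = guess_element(at$elesy, at$elety),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  waters_removed <- FALSE
  if (remove_waters) {
    atoms <- atoms[!(atoms$resid %in% WATER_RESIDUES), , drop = FALSE]
    waters_removed <- TRUE
  }
  atoms$featurizable <- atoms$resid %in% AA3
  if (!any(atoms$featurizable)) {
    stop("no standard amino-acid residues in ", path)
  }
  prot <- structure(
    list(
      atoms = atoms,
      resolution = read_pdb_resolution(path),
      waters_removed = waters_removed,
      hydrogens_present = any(atoms$element == "H")
    ),
    class = "protein_structure"
  )
  if (add_hydrogens) prot <- add_donor_hydrogens(prot)
  prot
}

# Resolution from the REMARK 2 header; bio3d does not surface it.
read_pdb_resolution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  m <- regmatches(rem[1], regexpr("[0-9]+\\.[0-9]+", rem[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to the first alphabetic character of the atom name
    el[miss] <- toupper(substr(gsub("[^A-Za-z].*", "", elety[miss]), 1, 1))
  }
  el
}

# Residue-level split helper: list of atom-index vectors keyed by
# chain|resno|resid, in file order.
residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "|")
  split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}

# Geometric hydrogen placement on donor N/O atoms lacking hydrogens.
add_donor_hydrogens <- function(prot) {
  atoms <- prot$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  new_rows <- list()
  for (idx in residue_index(atoms)) {
    res <- atoms$resid[idx[1]]
    if (!(res %in% AA3)) next
    donors <- donor_atom_names(res)
    for (i in idx) {
      if (!(atoms$elety[i] %in% donors)) next
      # skip if a hydrogen already sits on this donor
      d2 <- colSums((t(xyz) - xyz[i, ])^2)
      if (any(atoms$element == "H" & d2 < 1.3^2 & d2 > 0)) next
      nb <- idx[atoms$element[idx] != "H" &
                  colSums((t(xyz[idx, , drop = FALSE]) - xyz[i, ])^2) < 1.8^2]
      nb <- setdiff(nb, i)
      if (!length(nb)) next
      dir <- xyz[i, ] - colMeans(xyz[nb, , drop = FALSE])
      if (vnorm(dir) < 1e-6) next
      h <- xyz[i, ] + unit(dir) * 1.0
      new_rows[[length(new_rows) + 1]] <- data.frame(
        eleno = NA_integer_, elety = paste0("H", substr(atoms$elety[i], 2, 4)),
        element = "H", resid = res, chain = atoms$chain[i],
        resno = atoms$resno[i], x = h[1], y = h[2], z = h[3],
        featurizable = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(new_rows)) {
    atoms <- rbind(atoms, do.call(rbind, new_rows))
    atoms$eleno <- seq_len(nrow(atoms))
    prot$atoms <- atoms
  }
  prot$hydrogens_present <- any(prot$atoms$element == "H")
  prot
}

#' Read a ligand molecule from MOL2 or SDF
#'
#' MOL2 files are parsed with [bio3d::read.mol2()] (aromatic `ar` bond types
#' and the charge column are honoured); SDF/MOL files with
#' [ChemmineR::read.SDFset()], supplemented by the `M  CHG` block for formal
#' charges (ChemmineR drops it). Hydrogens are removed; only the heavy-atom
#' graph is kept. If the heavy-atom graph is disconnected, the largest
#' fragment is kept with a warning. Aromaticity is taken from file flags
#' (bond order 4 / type `ar`) and otherwise perceived from alternating
#' Kekule bond orders in 5- and 6-rings.
#'
#' @param path Path to a `.mol2`, `.sdf` or `.mol` file.
#' @return A `ligand_molecule`: list with `atoms` (data.frame: `element`,
#'   `x`, `y`, `z`, `charge`, `aromatic`), `bonds` (data.frame: `i`, `j`,
#'   `order`, `aromatic`), and `name`.
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) stop("ligand file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mol <- switch(ext,
    mol2 = read_ligand_mol2(path),
    sdf = ,
    mol = read_ligand_sdf(path),
    stop("unsupported ligand format '.", ext, "' (use .mol2, .sdf or .mol)")
  )
  mol <- strip_ligand_hydrogens(mol)
  mol <- keep_largest_fragment(mol)
  mol <- perceive_aromaticity(mol)
  validate_ligand(mol)
  mol
}

read_ligand_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
    error = function(e) stop("failed to parse MOL2 file '", path, "': ",
                             conditionMessage(e)))
  at <- m$atom
  element <- toupper(sub("\\..*$", "", at$elety))
  element <- paste0(substr(element, 1, 1), tolower(substr(element, 2, 2)))
  charge <- round(ifelse(is.na(at$charge), 0, at$charge))
  bonds <- m$bond
  arom_bond <- tolower(bonds$type) %in% c("ar", "am4")
  order <- suppressWarnings(as.numeric(bonds$type))
  order[is.na(order)] <- 1
  new_ligand(
    atoms = data.frame(
      element = element, x = at$x, y = at$y, z = at$z,
      charge = as.numeric(charge),
      aromatic = grepl("\\.ar$", tolower(at$elety)),
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(i = bonds$origin, j = bonds$target,
                       order = order, aromatic = arom_bond),
    name = m$name %||% basename(path)
  )
}

read_ligand_sdf <- function(path) {
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("failed to parse SDF file '", path, "': ",
                             conditionMessage(e)))
  if (length(sdfs) == 0) stop("no molecules in SDF file ", path)
  if (length(sdfs) > 1) {
    warning("multiple molecules in ", path, "; taking the first")
  }
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  charge <- numeric(nrow(ab))
  # formal charges live in the M  CHG property lines
  chg_lines <- grep("^M  CHG", readLines(path, warn = FALSE), value = TRUE)
  for (ln in chg_lines) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", ln)),
                             "\\s+")[[1]])
    if (length(f) >= 2) {
      pairs <- matrix(f, ncol = 2, byrow = TRUE)
      charge[pairs[, 1]] <- pairs[, 2]
    }
  }
  order <- as.numeric(bb[, 3])
  new_ligand(
    atoms = data.frame(
      element = element, x = ab[, 1], y = ab[, 2], z = ab[, 3],
      charge = charge, aromatic = FALSE, stringsAsFactors = FALSE
    ),
    bonds = data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                       order = ifelse(order == 4, 1, order),
                       aromatic = order == 4),
    name = ChemmineR::sdfid(sdf) %||% basename(path)
  )
}

new_ligand <- function(atoms, bonds, name = "ligand") {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "ligand_molecule")
}

validate_ligand <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb > 0) {
    if (any(mol$bonds$i < 1 | mol$bonds$i > nrow(mol$atoms)) ||
        any(mol$bonds$j < 1 | mol$bonds$j > nrow(mol$atoms))) {
      stop("bond indices reference non-existent atoms")
    }
  }
  if (any(!is.finite(as.matrix(mol$atoms[, c("x", "y", "z")])))) {
    stop("non-finite ligand coordinates")
  }
  invisible(mol)
}

strip_ligand_hydrogens <- function(mol) {
  keep <- toupper(mol$atoms$element) != "H"
  if (all(keep)) return(mol)
  map <- cumsum(keep)
  bonds <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
  bonds$i <- map[bonds$i]
  bonds$j <- map[bonds$j]
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- bonds
  mol
}

ligand_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

keep_largest_fragment <- function(mol) {
  n <- nrow(mol$atoms)
  if (n <= 1) return(mol)
  adj <- ligand_adjacency(mol)
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  if (cid == 1) return(mol)
  warning("ligand '", mol$name, "' has ", cid,
          " disconnected fragments; keeping the largest")
  keep <- comp == which.max(tabulate(comp))
  map <- cumsum(keep)
  bonds <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- bonds
  mol
}

# Mark atoms/bonds aromatic for 5/6-rings that either carry aromatic flags or
# show an alternating Kekule single/double pattern on a carbon/nitrogen ring.
perceive_aromaticity <- function(mol) {
  rings <- find_rings(mol, sizes = c(5, 6))
  if (!length(rings)) return(mol)
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (ring in rings) {
    k <- length(ring)
    eidx <- integer(k)
    for (t in seq_len(k)) {
      a <- ring[t]; b <- ring[t %% k + 1]
      eidx[t] <- match(paste(min(a, b), max(a, b)), bkey)
    }
    if (anyNA(eidx)) next
    ords <- mol$bonds$order[eidx]
    flagged <- all(mol$bonds$aromatic[eidx])
    kekule <- k == 6 &&
      all(mol$atoms$element[ring] %in% c("C", "N")) &&
      all(sort(ords) == c(1, 1, 1, 2, 2, 2)) &&
      all(abs(diff(c(ords, ords[1]))) == 1)
    if (flagged || kekule) {
      mol$atoms$aromatic[ring] <- TRUE
      mol$bonds$aromatic[eidx] <- TRUE
    }
  }
  mol
}

# All simple cycles of the requested sizes (each ring reported once, as an
# ordered vertex sequence).
find_rings <- function(mol, sizes = c(5, 6)) {
  adj <- ligand_adjacency(mol)
  n <- nrow(mol$atoms)
  out <- list()
  seen <- character(0)
  maxlen <- max(sizes)
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) >= 3) {
        if (length(path) %in% sizes) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            out[[length(out) + 1]] <<- path
          }
        }
      } else if (!(w %in% path) && length(path) < maxlen && w > path[1]) {
        walk(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  out
}

#' Filter complex records by resolution and affinity type
#'
#' Retains records whose crystallographic resolution is strictly below
#' `max_resolution` and whose affinity type is in `affinity_types`. Records
#' lacking a resolution (e.g. NMR structures) are dropped unless
#' `allow_missing_resolution = TRUE`. Input order is preserved and the filter
#' is idempotent.
#'
#' @param records A list of `complex_record` objects, or a data.frame with
#'   `resolution` and `affinity_type` columns (e.g. a complex index).
#' @param max_resolution Strict upper bound in Angstrom (default 2.5).
#' @param affinity_types Character set of admissible label types
#'   (default `c("Kd", "Ki")`; IC50 entries are excluded from training).
#' @param allow_missing_resolution Keep records without a resolution.
#' @return The filtered records, same container type as the input.
#' @export
filter_complexes <- function(records, max_resolution = 2.5,
                             affinity_types = c("Kd", "Ki"),
                             allow_missing_resolution = FALSE) {
  get <- function(field) {
    if (is.data.frame(records)) records[[field]]
    else vapply(records, function(r) {
      v <- r[[field]]
      if (is.null(v) || length(v) == 0) NA else v
    }, if (field == "resolution") numeric(1) else character(1))
  }
  res <- suppressWarnings(as.numeric(get("resolution")))
  typ <- as.character(get("affinity_type"))
  keep_res <- ifelse(is.na(res), allow_missing_resolution, res < max_resolution)
  keep <- keep_res & !is.na(typ) & typ %in% affinity_types
  if (is.data.frame(records)) records[keep, , drop = FALSE] else records[keep]
}

#' Read a complex index file
#'
#' The index is a CSV with columns `id`, `protein_path`, `ligand_path`,
#' `affinity`, `affinity_type`, `resolution`. Relative paths are resolved
#' against the directory of the index file.
#'
#' @param path Path to the CSV index.
#' @return A data.frame with the six columns above.
#' @export
read_complex_index <- function(path) {
  idx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "protein_path", "ligand_path", "affinity", "affinity_type")
  miss <- setdiff(need, names(idx))
  if (length(miss)) stop("index is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(idx$resolution)) idx$resolution <- NA_real_
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  idx$protein_path <- fix(idx$protein_path)
  idx$ligand_path <- fix(idx$ligand_path)
  idx
}

#' Load the structures referenced by an index into complex records
#'
#' @param index Data frame from [read_complex_index()].
#' @param add_hydrogens,remove_waters Passed to [read_protein()].
#' @return List of `complex_record` objects (id, protein, ligand, affinity,
#'   affinity_type, resolution).
#' @export
load_complexes <- function(index, add_hydrogens = FALSE, remove_waters = TRUE) {
  lapply(seq_len(nrow(index)), function(k) {
    structure(list(
      id = index$id[k],
      protein = read_protein(index$protein_path[k],
                             add_hydrogens = add_hydrogens,
                             remove_waters = remove_waters),
      ligand = read_ligand(index$ligand_path[k]),
      affinity = index$affinity[k],
      affinity_type = index$affinity_type[k],
      resolution = index$resolution[k]
    ), class = "complex_record")
  })
}

# Writers --------------------------------------------------------------------

#' Write a protein structure as a PDB file
#'
#' Fixed-width ATOM records; used by the fixture generator so that synthetic
#' complexes exercise the real PDB reader.
#'
#' @param prot A `protein_structure`.
#' @param path Output path.
#' @param resolution If non-`NA`, written as a REMARK 2 header line.
#' @return `path`, invisibly.
#' @export
write_protein_pdb <- function(prot, path, resolution = prot$resolution) {
  a <- prot$atoms
  lines <- character(0)
  if (!is.null(resolution) && !is.na(resolution)) {
    lines <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution)
  }
  name4 <- ifelse(nchar(a$elety) < 4,
                  sprintf(" %-3s", a$elety), substr(a$elety, 1, 4))
  rec <- ifelse(a$resid %in% c(AA3, WATER_RESIDUES), "ATOM  ", "HETATM")
  lines <- c(lines, sprintf(
    "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, 1.0, 0.0, a$element
  ), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ligand molecule as a MOL2 file
#'
#' SYBYL atom types are derived from element, aromatic flag and formal charge
#' (`C.ar`/`N.ar` for aromatic atoms, `O.co2` for carboxylate-like oxygens);
#' formal charges go in the charge column; aromatic bonds use type `ar`.
#'
#' @param mol A `ligand_molecule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_mol2 <- function(mol, path) {
  a <- mol$atoms
  b <- mol$bonds
  sybyl <- mapply(function(el, ar, ch) {
    if (ar && el %in% c("C", "N")) return(paste0(el, ".ar"))
    if (el == "O" && ch < 0) return("O.co2")
    if (el == "N" && ch > 0) return("N.4")
    if (el %in% c("C", "N", "O", "S", "P")) return(paste0(el, ".3"))
    el
  }, a$element, a$aromatic, a$charge)
  lines <- c(
    "@<TRIPOS>MOLECULE", mol$name,
    sprintf(" %d %d 0 0 0", nrow(a), nrow(b)),
    "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
    sprintf("%4d %-4s %9.4f %9.4f %9.4f %-6s %d LIG %8.4f",
            seq_len(nrow(a)), paste0(a$element, seq_len(nrow(a))),
            a$x, a$y, a$z, sybyl, 1L, a$charge),
    "@<TRIPOS>BOND",
    if (nrow(b)) sprintf("%4d %4d %4d %s", seq_len(nrow(b)), b$i, b$j,
                         ifelse(b$aromatic, "ar", as.character(b$order)))
  )
  writeLines(lines, path)
  invisible(path)
}
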