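# Substructural molecular fragment descriptors of the ligand:
# linear atom sequences (simple paths of 2-6 heavy atoms) and augmented atoms
# (one centre plus the multiset of its bonded neighbours).
#
# Label grammar: element symbols, lower-cased when the atom is aromatic;
# bond symbols "-", "=", "#" by order and ":" for aromatic bonds. Sequence
# labels are canonicalized as the lexicographic minimum of the forward and
# reverse rendering; augmented labels sort their neighbour terms. Hydrogens
# are excluded throughout (heavy-atom graph only); counts are occurrence
# numbers, not binary presence.

frag_atom_symbol <- function(mol) {
  ifelse(mol$atoms$aromatic, tolower(mol$atoms$element), mol$atoms$element)
}

frag_bond_symbol <- function(order, aromatic) {
  ifelse(aromatic, ":",
         ifelse(order >= 3, "#", ifelse(order == 2, "=", "-")))
}

# adjacency with bond symbols: list of data.frames (to, sym)
frag_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(data.frame(to = integer(0), sym = character(0))), n)
  b <- mol$bonds
  if (nrow(b)) {
    sym <- frag_bond_symbol(b$order, b$aromatic)
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- rbind(adj[[b$i[k]]],
                             data.frame(to = b$j[k], sym = sym[k]))
      adj[[b$j[k]]] <- rbind(adj[[b$j[k]]],
                             data.frame(to = b$i[k], sym = sym[k]))
    }
  }
  adj
}

render_path <- function(atoms_sym, bond_syms) {
  k <- length(atoms_sym)
  if (k == 1) return(atoms_sym)
  out <- character(2 * k - 1)
  out[seq(1, 2 * k - 1, by = 2)] <- atoms_sym
  out[seq(2, 2 * k - 2, by = 2)] <- bond_syms
  paste(out, collapse = "")
}

#' Enumerate linear atom-sequence fragments
#'
#' All simple paths of `min_atoms` to `max_atoms` heavy atoms; each
#' undirected path is counted once, with the canonical label being the
#' lexicographic minimum of the forward and reverse renderings.
#'
#' @param mol A `ligand_molecule`.
#' @param min_atoms,max_atoms Path length bounds in atoms (defaults 2 and 6).
#' @return Named integer vector: canonical label -> occurrence count.
#'   Empty for a single-atom molecule.
#' @export
#' @examples
#' # a three-atom chain C-C-O has paths C-C, C-O and C-C-O
enumerate_sequences <- function(mol, min_atoms = 2, max_atoms = 6) {
  n <- nrow(mol$atoms)
  if (n < 2 || min_atoms > max_atoms) return(integer(0))
  sym <- frag_atom_symbol(mol)
  adj <- frag_adjacency(mol)
  labels <- character(0)
  walk <- function(path, bonds) {
    k <- length(path)
    if (k >= min_atoms && path[1] < path[k]) {
      fwd <- render_path(sym[path], bonds)
      rev_ <- render_path(sym[rev(path)], rev(bonds))
      labels[[length(labels) + 1]] <<- min(fwd, rev_)
    }
    if (k == max_atoms) return()
    nb <- adj[[path[k]]]
    for (t in seq_len(nrow(nb))) {
      w <- nb$to[t]
      if (!(w %in% path)) walk(c(path, w), c(bonds, nb$sym[t]))
    }
  }
  for (s in seq_len(n)) walk(s, character(0))
  if (!length(labels)) return(integer(0))
  tab <- table(labels)
  counts <- setNames(as.integer(tab), names(tab))
  counts[sort(names(counts), method = "radix")]
}

#' Enumerate augmented-atom fragments
#'
#' One fragment per heavy atom: the centre's symbol followed by the sorted
#' multiset of `(bond symbol, neighbour symbol)` terms, e.g. the central
#' carbon of ethanol is `C(-C)(-O)` and every benzene carbon is `c(:c)(:c)`.
#' An isolated atom's label is just its symbol.
#'
#' @param mol A `ligand_molecule`.
#' @return Named integer vector: canonical label -> count.
#' @export
enumerate_augmented <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0) return(integer(0))
  sym <- frag_atom_symbol(mol)
  adj <- frag_adjacency(mol)
  labels <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    if (!nrow(nb)) return(sym[i])
    terms <- sort(paste0("(", nb$sym, sym[nb$to], ")"), method = "radix")
    paste0(sym[i], paste(terms, collapse = ""))
  }, character(1))
  tab <- table(labels)
  counts <- setNames(as.integer(tab), names(tab))
  counts[sort(names(counts), method = "radix")]
}

#' Build a fragment dictionary over a training set of ligands
#'
#' Union of both fragment families over all molecules, indexed
#' lexicographically (locale-independent radix sort), hence deterministic
#' across runs and invariant to the order of the molecule collection.
#'
#' @param mols Non-empty list of `ligand_molecule` objects.
#' @param min_atoms,max_atoms Sequence-path bounds, see
#'   [enumerate_sequences()].
#' @return A `fragment_dictionary`: list with `labels` (sorted character
#'   vector; the column index of label `labels[k]` is `k - 1`) and
#'   `source_size` (number of training molecules).
#' @export
build_fragment_dictionary <- function(mols, min_atoms = 2, max_atoms = 6) {
  if (!length(mols)) stop("cannot build a fragment dictionary from zero molecules")
  labs <- unique(unlist(lapply(mols, function(m) {
    c(names(enumerate_sequences(m, min_atoms, max_atoms)),
      names(enumerate_augmented(m)))
  })))
  structure(
    list(labels = sort(labs, method = "radix"), source_size = length(mols),
         min_atoms = min_atoms, max_atoms = max_atoms),
    class = "fragment_dictionary"
  )
}

#' @export
length.fragment_dictionary <- function(x) length(x$labels)

#' Count a ligand's fragments against a dictionary
#'
#' Fragments absent from the dictionary are ignored (the dictionary is frozen
#' at training time); their number is reported via the `n_unseen` attribute
#' and a message.
#'
#' @param mol A `ligand_molecule`.
#' @param dict A [build_fragment_dictionary()] result.
#' @return Named integer count vector of length `length(dict)`.
#' @export
vectorize_fragments <- function(mol, dict) {
  stopifnot(inherits(dict, "fragment_dictionary"))
  counts <- c(enumerate_sequences(mol, dict$min_atoms, dict$max_atoms),
              enumerate_augmented(mol))
  out <- setNames(integer(length(dict$labels)), dict$labels)
  hit <- names(counts) %in% dict$labels
  if (any(!hit)) {
    message(sum(!hit), " fragment label(s) of '", mol$name,
            "' not in dictionary; ignored")
  }
  out[names(counts)[hit]] <- as.integer(counts[hit])
  attr(out, "n_unseen") <- sum(!hit)
  out
}

#' Write a fragment dictionary to JSON
#'
#' Serialized as `label -> 0-based column index` plus provenance
#' (`source_size`, path bounds, content hash).
#'
#' @param dict A `fragment_dictionary`.
#' @param path Output path.
#' @export
write_fragment_dictionary <- function(dict, path) {
  jsonlite::write_json(
    list(entries = setNames(as.list(seq_along(dict$labels) - 1L), dict$labels),
         source_size = dict$source_size,
         min_atoms = dict$min_atoms, max_atoms = dict$max_atoms,
         hash = dictionary_hash(dict)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fragment dictionary from JSON
#' @param path Path written by [write_fragment_dictionary()].
#' @export
read_fragment_dictionary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- unlist(j$entries)
  structure(
    list(labels = names(sort(idx)), source_size = j$source_size,
         min_atoms = j$min_atoms %||% 2, max_atoms = j$max_atoms %||% 6),
    class = "fragment_dictionary"
  )
}

dictionary_hash <- function(dict) {
  if (is.null(dict)) return(NA_character_)
  rlang::hash(dict$labels)
}
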