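# Feature-set composition, labeled datasets and seeded splits.

FEATURE_SETS <- c("ifp", "ifp+dist", "ifp+frag", "ifp+dist+frag")

normalize_feature_set <- function(name) {
  key <- gsub("[ _]", "", tolower(name))
  key <- sub("\\+int-?dist", "+dist", key)
  if (!(key %in% FEATURE_SETS)) {
    stop("unknown feature set '", name, "'; use one of: ",
         paste(FEATURE_SETS, collapse = ", "))
  }
  key
}

#' Compose a per-complex feature row
#'
#' Concatenates the requested components in the fixed order fingerprint,
#' then distances, then fragments. The four feature sets are `"ifp"` (140),
#' `"ifp+dist"` (280), `"ifp+frag"` (140 + dictionary size) and
#' `"ifp+dist+frag"` (280 + dictionary size).
#'
#' @param ifp 140-cell count vector from [build_ifp()].
#' @param intdist 140-cell distance vector from [build_intdist()]; required
#'   by the `+dist` sets.
#' @param frag Fragment count vector from [vectorize_fragments()]; required
#'   by the `+frag` sets.
#' @param feature_set One of the four set names.
#' @return Named numeric vector of the documented dimension.
#' @export
assemble_features <- function(ifp, intdist = NULL, frag = NULL,
                              feature_set = "ifp") {
  feature_set <- normalize_feature_set(feature_set)
  if (missing(ifp) || is.null(ifp)) stop("feature set '", feature_set,
                                         "' requires the ifp component")
  stopifnot(length(ifp) == 140)
  out <- as.numeric(ifp)
  names(out) <- names(ifp)
  if (grepl("dist", feature_set)) {
    if (is.null(intdist)) stop("feature set '", feature_set,
                               "' requires the intdist component")
    stopifnot(length(intdist) == 140)
    out <- c(out, setNames(as.numeric(intdist), names(intdist)))
  }
  if (grepl("frag", feature_set)) {
    if (is.null(frag)) stop("feature set '", feature_set,
                            "' requires the frag component")
    out <- c(out, setNames(as.numeric(frag), names(frag)))
  }
  out
}

#' Featurize one protein-ligand complex
#'
#' Runs interaction detection and (if requested) fragment counting, then
#' assembles the feature row.
#'
#' @param protein,ligand Structures as returned by [read_protein()] /
#'   [read_ligand()].
#' @param feature_set One of `"ifp"`, `"ifp+dist"`, `"ifp+frag"`,
#'   `"ifp+dist+frag"`.
#' @param rules Detection thresholds, see [geometric_rules()].
#' @param dictionary Fragment dictionary; required by the `+frag` sets.
#' @return Named numeric feature row.
#' @export
featurize_complex <- function(protein, ligand, feature_set = "ifp",
                              rules = geometric_rules(), dictionary = NULL) {
  feature_set <- normalize_feature_set(feature_set)
  recs <- detect_interactions(protein, ligand, rules)
  frag <- NULL
  if (grepl("frag", feature_set)) {
    if (is.null(dictionary)) stop("feature set '", feature_set,
                                  "' requires a fragment dictionary")
    frag <- vectorize_fragments(ligand, dictionary)
  }
  assemble_features(build_ifp(recs), build_intdist(recs), frag, feature_set)
}

#' Construct a labeled dataset
#'
#' @param ids Complex identifiers (row names of the feature matrix).
#' @param features Numeric matrix, one row per complex.
#' @param labels pKd/pKi values, one per row.
#' @param feature_set Which feature composition the columns hold.
#' @param dictionary Fragment dictionary used (or `NULL`).
#' @return A `labeled_dataset`.
#' @export
make_labeled_dataset <- function(ids, features, labels, feature_set = "ifp",
                                 dictionary = NULL) {
  features <- as.matrix(features)
  if (length(ids) != nrow(features) || length(labels) != nrow(features)) {
    stop("ids, feature rows and labels must have equal length")
  }
  if (anyNA(features) || anyNA(labels)) stop("dataset contains missing values")
  if (any(!is.finite(labels))) stop("labels must be finite")
  rownames(features) <- ids
  structure(
    list(ids = as.character(ids), features = features,
         labels = as.numeric(labels),
         feature_set = normalize_feature_set(feature_set),
         dictionary = dictionary),
    class = "labeled_dataset"
  )
}

#' Featurize an index of complexes into a labeled dataset
#'
#' @param index Data frame from [read_complex_index()].
#' @param feature_set,rules,dictionary See [featurize_complex()].
#' @param add_hydrogens Passed to [read_protein()].
#' @return A `labeled_dataset` with one row per index entry.
#' @export
featurize_index <- function(index, feature_set = "ifp",
                            rules = geometric_rules(), dictionary = NULL,
                            add_hydrogens = FALSE) {
  rows <- lapply(load_complexes(index, add_hydrogens = add_hydrogens),
                 function(cr) featurize_complex(cr$protein, cr$ligand,
                                                feature_set, rules, dictionary))
  make_labeled_dataset(index$id, do.call(rbind, rows), index$affinity,
                       feature_set, dictionary)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

subset_dataset <- function(ds, idx) {
  make_labeled_dataset(ds$ids[idx], ds$features[idx, , drop = FALSE],
                       ds$labels[idx], ds$feature_set, ds$dictionary)
}

#' Seeded train/validation split
#'
#' Disjoint and exhaustive random partition, reproducible for a given seed
#' (the caller's RNG state is untouched). The train fraction is honoured to
#' rounding.
#'
#' @param ds A `labeled_dataset` with at least 2 rows.
#' @param ratio Train fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `train` and `valid` (both `labeled_dataset`).
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 1) {
  n <- nrow(ds$features)
  if (n < 2) stop("need at least 2 rows to split")
  n_train <- round(n * ratio)
  if (n_train < 1 || n_train >= n) {
    stop("degenerate split: ", n_train, " of ", n, " rows in train")
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = subset_dataset(ds, sort(idx)),
       valid = subset_dataset(ds, sort(setdiff(seq_len(n), idx))))
}

#' Remove test-set overlap from a training id list
#'
#' Set difference with input order preserved.
#'
#' @param train_ids,test_ids Character vectors of complex ids.
#' @return `train_ids` without any id present in `test_ids`.
#' @export
remove_overlap <- function(train_ids, test_ids) {
  train_ids[!(train_ids %in% test_ids)]
}

#' Write a feature matrix (plus labels) as CSV
#'
#' Deterministic layout: `id`, `label`, then one column per feature name.
#'
#' @param ds A `labeled_dataset`.
#' @param path Output path.
#' @export
write_feature_csv <- function(ds, path) {
  df <- data.frame(id = ds$ids, label = ds$labels, ds$features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a split manifest as JSON (seed plus id lists)
#' @param split Result of [split_dataset()].
#' @param seed The seed that produced the split.
#' @param path Output path.
#' @export
write_split_manifest <- function(split, seed, path) {
  jsonlite::write_json(
    list(seed = seed, train_ids = split$train$ids, valid_ids = split$valid$ids),
    path, auto_unbox = TRUE)
  invisible(path)
}
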