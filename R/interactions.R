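# Geometric detection of the seven protein-ligand interaction classes and
# their reduction to the 140-cell fingerprint / distance vectors.

#' Geometric detection rules
#'
#' Default thresholds follow community-standard interaction-fingerprint
#' practice: hydrophobic carbon-carbon contacts within 4.5 A; face-to-face
#' stacking with ring centroids within 4.0 A and interplanar angle at most
#' 30 degrees; edge-to-face with centroids within 5.5 A and angle between 60
#' and 90 degrees; hydrogen bonds with donor-acceptor distance at most 3.5 A
#' and, when the donor hydrogen is present, D-H...A angle at least 120
#' degrees; ionic contacts between opposite formal charges within 4.0 A.
#' All values are configurable and are recorded in detection output metadata.
#'
#' @param hydrophobic_cutoff,ionic_cutoff,hbond_da_cutoff Distance cutoffs (A).
#' @param f2f_centroid_cutoff,e2f_centroid_cutoff Ring-centroid cutoffs (A).
#' @param f2f_plane_angle_max Maximum interplanar angle for face-to-face (deg).
#' @param e2f_plane_angle_min Minimum interplanar angle for edge-to-face (deg).
#' @param hbond_dha_angle_min Minimum D-H...A angle when hydrogens exist (deg).
#' @return A `geometric_rules` list.
#' @export
geometric_rules <- function(hydrophobic_cutoff = 4.5,
                            f2f_centroid_cutoff = 4.0,
                            f2f_plane_angle_max = 30,
                            e2f_centroid_cutoff = 5.5,
                            e2f_plane_angle_min = 60,
                            hbond_da_cutoff = 3.5,
                            hbond_dha_angle_min = 120,
                            ionic_cutoff = 4.0) {
  rules <- list(
    hydrophobic_cutoff = hydrophobic_cutoff,
    f2f_centroid_cutoff = f2f_centroid_cutoff,
    f2f_plane_angle_max = f2f_plane_angle_max,
    e2f_centroid_cutoff = e2f_centroid_cutoff,
    e2f_plane_angle_min = e2f_plane_angle_min,
    hbond_da_cutoff = hbond_da_cutoff,
    hbond_dha_angle_min = hbond_dha_angle_min,
    ionic_cutoff = ionic_cutoff
  )
  stopifnot(all(unlist(rules) > 0),
            f2f_plane_angle_max <= 90, e2f_plane_angle_min <= 90)
  structure(rules, class = "geometric_rules")
}

#' Write geometric rules to JSON
#' @param rules A `geometric_rules` object.
#' @param path Output path.
#' @export
write_rules_json <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read geometric rules from JSON
#' @param path Path to a JSON file written by [write_rules_json()].
#' @export
read_rules_json <- function(path) {
  do.call(geometric_rules, jsonlite::read_json(path, simplifyVector = TRUE))
}

empty_records <- function() {
  data.frame(residue_name = character(0), chain = character(0),
             resno = integer(0), interaction_class = character(0),
             distance = numeric(0), stringsAsFactors = FALSE)
}

#' Detect protein-ligand interactions
#'
#' Evaluates all residue/ligand contacts pairwise under the geometric rules
#' and emits one record per (residue, class, protein functional group)
#' event: each protein donor or acceptor atom, each charged group and each
#' aromatic ring counts as one functional group; the hydrophobic surface of a
#' residue counts once. The recorded distance is the minimal qualifying
#' atom-atom distance for the event (centroid-centroid for aromatic
#' classes). Hydrogen-bond direction determines the class
#' (`HBOND_ACC_LIG`: protein donates, ligand accepts); the sign of the
#' ligand's charge determines `IONIC_LIG_NEG` vs `IONIC_LIG_POS`. Contacts
#' between an aromatic residue (PHE/TYR/TRP/HIS) and ligand aromatic-ring
#' atoms are described exclusively by the stacking classes: they are never
#' double-counted as hydrophobic, a structural rule that keeps every
#' fingerprint cell monotone under shrinking cutoffs.
#'
#' @param protein A `protein_structure` (typed automatically if needed).
#' @param ligand A `ligand_molecule` (typed automatically if needed).
#' @param rules A [geometric_rules()] object.
#' @return A data.frame of interaction records (`residue_name`, `chain`,
#'   `resno`, `interaction_class`, `distance`) with the rules attached as the
#'   `"rules"` attribute.
#' @export
detect_interactions <- function(protein, ligand, rules = geometric_rules()) {
  if (!inherits(protein, "typed_protein")) protein <- assign_atom_types(protein)
  if (!inherits(ligand, "typed_ligand")) ligand <- assign_atom_types(ligand)
  tp <- protein$typing
  tl <- ligand$typing
  pxyz <- tp$xyz
  lxyz <- tl$xyz

  lig_ring_info <- lapply(tl$rings, function(r)
    list(idx = r, centroid = ring_centroid(lxyz, r),
         normal = ring_normal(lxyz, r)))
  lig_ring_atoms <- unique(unlist(tl$rings))

  recs <- list()
  add <- function(res, class, dist) {
    recs[[length(recs) + 1]] <<- data.frame(
      residue_name = res$resid, chain = res$chain, resno = res$resno,
      interaction_class = class, distance = dist, stringsAsFactors = FALSE)
  }
  atom_dists <- function(p_idx, l_idx) {
    # |p_idx| x |l_idx| distance matrix
    pm <- pxyz[p_idx, , drop = FALSE]
    lm <- lxyz[l_idx, , drop = FALSE]
    d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
    sqrt(pmax(d2, 0))
  }

  for (res in tp$residues) {
    # ionic -----------------------------------------------------------------
    for (pg in res$cation_groups) {
      for (lg in tl$anion_groups) {
        d <- min(atom_dists(pg, lg))
        if (d <= rules$ionic_cutoff) add(res, "IONIC_LIG_NEG", d)
      }
    }
    for (pg in res$anion_groups) {
      for (lg in tl$cation_groups) {
        d <- min(atom_dists(pg, lg))
        if (d <= rules$ionic_cutoff) add(res, "IONIC_LIG_POS", d)
      }
    }

    # aromatic stacking ------------------------------------------------------
    for (pr in res$rings) {
      pc <- ring_centroid(pxyz, pr)
      pn <- ring_normal(pxyz, pr)
      for (lr in lig_ring_info) {
        d <- vnorm(pc - lr$centroid)
        ang <- vec_angle(pn, lr$normal)
        ang <- min(ang, 180 - ang)  # plane angle in [0, 90]
        if (d <= rules$f2f_centroid_cutoff && ang <= rules$f2f_plane_angle_max) {
          add(res, "AR_F2F", d)
        } else if (d <= rules$e2f_centroid_cutoff &&
                   ang >= rules$e2f_plane_angle_min) {
          add(res, "AR_E2F", d)
        }
      }
    }

    # hydrogen bonds ----------------------------------------------------------
    if (length(res$donors) && length(tl$acceptors)) {
      dm <- atom_dists(res$donors, tl$acceptors)
      for (a in seq_along(res$donors)) {
        ok <- which(dm[a, ] <= rules$hbond_da_cutoff)
        if (length(res$hydrogens)) {
          don <- res$donors[a]
          hs <- res$hydrogens[
            sqrt(colSums((t(pxyz[res$hydrogens, , drop = FALSE]) -
                            pxyz[don, ])^2)) < 1.3]
          if (length(hs)) {
            ok <- ok[vapply(ok, function(ai) {
              acc <- tl$acceptors[ai]
              any(vapply(hs, function(h)
                vec_angle(pxyz[don, ] - pxyz[h, ],
                          lxyz[acc, ] - pxyz[h, ]) >= rules$hbond_dha_angle_min,
                logical(1)))
            }, logical(1))]
          }
        }
        if (length(ok)) add(res, "HBOND_ACC_LIG", min(dm[a, ok]))
      }
    }
    if (length(res$acceptors) && length(tl$donors)) {
      dm <- atom_dists(res$acceptors, tl$donors)
      for (a in seq_along(res$acceptors)) {
        d <- min(dm[a, ])
        if (d <= rules$hbond_da_cutoff) add(res, "HBOND_DON_LIG", d)
      }
    }

    # hydrophobic -------------------------------------------------------------
    lig_h <- if (length(res$rings)) setdiff(tl$hydrophobic, lig_ring_atoms)
             else tl$hydrophobic
    if (length(res$hydrophobic) && length(lig_h)) {
      d <- min(atom_dists(res$hydrophobic, lig_h))
      if (d <= rules$hydrophobic_cutoff) add(res, "HYDROPHOBIC", d)
    }
  }

  out <- if (length(recs)) do.call(rbind, recs) else empty_records()
  rownames(out) <- NULL
  attr(out, "rules") <- rules
  out
}

#' Fold interaction records into the 140-cell fingerprint count vector
#'
#' Cell (amino acid, class) holds the number of records in that cell;
#' distinct residues of the same name count separately (two arginines each
#' hydrogen-bonded to the ligand give the ARG H-bond cell the value 2).
#' Records with a non-standard residue name are skipped with a warning.
#'
#' @param records Data frame from [detect_interactions()].
#' @return Named integer vector of length 140 in the canonical
#'   [ifp_feature_names()] order; its sum equals the number of featurized
#'   records.
#' @export
build_ifp <- function(records) {
  bad <- !(records$residue_name %in% AA3)
  if (any(bad)) {
    warning("skipping ", sum(bad), " record(s) with non-standard residues: ",
            paste(unique(records$residue_name[bad]), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  tab <- table(factor(records$residue_name, levels = AA3),
               factor(records$interaction_class, levels = INTERACTION_CLASSES))
  setNames(as.integer(t(tab)), ifp_feature_names())
}

#' Fold interaction records into the 140-cell contact-distance vector
#'
#' Each cell holds the minimum distance (A) over the records in that cell
#' (the closest contact governs the interaction energetics) and 0.0 where no
#' interaction of that cell exists, so a cell is positive exactly when the
#' corresponding fingerprint count is positive.
#'
#' @inheritParams build_ifp
#' @return Named numeric vector of length 140 (names carry a `_dist` suffix).
#' @export
build_intdist <- function(records) {
  records <- records[records$residue_name %in% AA3, , drop = FALSE]
  out <- setNames(numeric(140), ifp_feature_names(distances = TRUE))
  if (nrow(records)) {
    cell <- paste0(records$residue_name, "_", records$interaction_class, "_dist")
    mins <- tapply(records$distance, cell, min)
    out[names(mins)] <- as.numeric(mins)
  }
  out
}

#' Write a per-complex interaction profile
#'
#' Tab-separated report (residue, chain, residue number, interaction class,
#' distance) -- the interpretability surface used to compare e.g. docked
#' versus crystal poses residue by residue.
#'
#' @param records Data frame from [detect_interactions()].
#' @param path Output TSV path.
#' @export
write_interaction_profile <- function(records, path) {
  ord <- order(records$chain, records$resno,
               match(records$interaction_class, INTERACTION_CLASSES))
  write.table(records[ord, , drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
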