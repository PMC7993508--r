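# Independent brute-force oracles. These deliberately avoid the package's
# detection/enumeration code paths: plain nested loops, no vectorized
# distance matrices, cross-product ring normals instead of SVD.

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

oracle_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

# all-pairs interaction detector over typed structures
oracle_detect <- function(protein, ligand, rules = geometric_rules()) {
  if (!inherits(protein, "typed_protein")) protein <- assign_atom_types(protein)
  if (!inherits(ligand, "typed_ligand")) ligand <- assign_atom_types(ligand)
  tp <- protein$typing
  tl <- ligand$typing
  px <- tp$xyz
  lx <- tl$xyz
  rows <- list()
  emit <- function(res, cls, d) {
    rows[[length(rows) + 1]] <<- data.frame(
      residue_name = res$resid, chain = res$chain, resno = res$resno,
      interaction_class = cls, distance = d, stringsAsFactors = FALSE)
  }
  group_min <- function(p_idx, l_idx) {
    best <- Inf
    for (i in p_idx) for (j in l_idx) {
      d <- oracle_dist(px[i, ], lx[j, ])
      if (d < best) best <- d
    }
    best
  }
  ring_geo <- function(xyz, idx) {
    c0 <- colMeans(xyz[idx, , drop = FALSE])
    v1 <- xyz[idx[2], ] - xyz[idx[1], ]
    v2 <- xyz[idx[3], ] - xyz[idx[1], ]
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    list(centroid = c0, normal = n)
  }
  for (res in tp$residues) {
    for (pg in res$cation_groups) for (lg in tl$anion_groups) {
      d <- group_min(pg, lg)
      if (d <= rules$ionic_cutoff) emit(res, "IONIC_LIG_NEG", d)
    }
    for (pg in res$anion_groups) for (lg in tl$cation_groups) {
      d <- group_min(pg, lg)
      if (d <= rules$ionic_cutoff) emit(res, "IONIC_LIG_POS", d)
    }
    for (pr in res$rings) {
      pg <- ring_geo(px, pr)
      for (lr in tl$rings) {
        lg <- ring_geo(lx, lr)
        d <- oracle_dist(pg$centroid, lg$centroid)
        ang <- oracle_angle(pg$normal, lg$normal)
        ang <- min(ang, 180 - ang)
        if (d <= rules$f2f_centroid_cutoff && ang <= rules$f2f_plane_angle_max) {
          emit(res, "AR_F2F", d)
        } else if (d <= rules$e2f_centroid_cutoff &&
                   ang >= rules$e2f_plane_angle_min) {
          emit(res, "AR_E2F", d)
        }
      }
    }
    # aromatic residues never count ligand ring atoms as hydrophobic
    stacked <- if (length(res$rings)) unique(unlist(tl$rings)) else integer(0)
    for (don in res$donors) {
      hs <- integer(0)
      for (h in res$hydrogens) {
        if (oracle_dist(px[h, ], px[don, ]) < 1.3) hs <- c(hs, h)
      }
      best <- Inf
      for (acc in tl$acceptors) {
        d <- oracle_dist(px[don, ], lx[acc, ])
        if (d > rules$hbond_da_cutoff) next
        if (length(hs)) {
          ok <- FALSE
          for (h in hs) {
            if (oracle_angle(px[don, ] - px[h, ], lx[acc, ] - px[h, ]) >=
                rules$hbond_dha_angle_min) ok <- TRUE
          }
          if (!ok) next
        }
        if (d < best) best <- d
      }
      if (is.finite(best)) emit(res, "HBOND_ACC_LIG", best)
    }
    for (acc in res$acceptors) {
      best <- Inf
      for (don in tl$donors) {
        d <- oracle_dist(px[acc, ], lx[don, ])
        if (d <= rules$hbond_da_cutoff && d < best) best <- d
      }
      if (is.finite(best)) emit(res, "HBOND_DON_LIG", best)
    }
    best <- Inf
    for (i in res$hydrophobic) for (j in setdiff(tl$hydrophobic, stacked)) {
      d <- oracle_dist(px[i, ], lx[j, ])
      if (d < best) best <- d
    }
    if (best <= rules$hydrophobic_cutoff) emit(res, "HYDROPHOBIC", best)
  }
  out <- if (length(rows)) do.call(rbind, rows) else plifr:::empty_records()
  rownames(out) <- NULL
  out
}

sort_records <- function(recs) {
  recs <- recs[order(recs$chain, recs$resno, recs$interaction_class,
                     recs$distance), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

expect_same_records <- function(a, b, tol = 1e-9) {
  a <- sort_records(a)
  b <- sort_records(b)
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$residue_name, b$residue_name)
  expect_identical(a$interaction_class, b$interaction_class)
  expect_equal(a$distance, b$distance, tolerance = tol)
}

# brute-force sequence-fragment counts via igraph simple paths
oracle_sequence_counts <- function(mol, min_atoms = 2, max_atoms = 6) {
  g <- igraph::graph_from_edgelist(
    as.matrix(mol$bonds[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mol$atoms) - igraph::vcount(g)))
  sym <- ifelse(mol$atoms$aromatic, tolower(mol$atoms$element),
                mol$atoms$element)
  bsym <- matrix(NA_character_, nrow(mol$atoms), nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    s <- if (mol$bonds$aromatic[k]) ":" else
      c("-", "=", "#")[min(mol$bonds$order[k], 3)]
    bsym[mol$bonds$i[k], mol$bonds$j[k]] <- s
    bsym[mol$bonds$j[k], mol$bonds$i[k]] <- s
  }
  labels <- character(0)
  n <- nrow(mol$atoms)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- igraph::all_simple_paths(g, from = s, to = t,
                                      cutoff = max_atoms - 1)
    for (p in paths) {
      p <- as.integer(p)
      if (length(p) < min_atoms || length(p) > max_atoms) next
      render <- function(q) {
        parts <- sym[q[1]]
        for (k in 2:length(q)) {
          parts <- c(parts, bsym[q[k - 1], q[k]], sym[q[k]])
        }
        paste(parts, collapse = "")
      }
      labels <- c(labels, min(render(p), render(rev(p))))
    }
  }
  if (!length(labels)) return(integer(0))
  tab <- table(labels)
  counts <- setNames(as.integer(tab), names(tab))
  counts[sort(names(counts), method = "radix")]
}
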