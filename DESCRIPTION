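Package: plifr
Title: Protein-Ligand Interaction Fingerprints and Fragment-Based Affinity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable binding-affinity scoring models for
    protein-ligand complexes. Detects seven classes of protein-ligand
    interactions (hydrophobic, face-to-face and edge-to-face aromatic
    stacking, hydrogen bonds in both directions, and ionic contacts of
    either sign) under configurable geometric rules and folds them into a
    per-residue interaction-fingerprint count vector (20 amino acids x 7
    classes = 140 cells) with a companion vector of contact distances.
    Ligands are additionally described by substructural molecular fragment
    counts (linear atom sequences of two to six atoms and augmented atoms).
    Random-forest and deep-network regressors map these features to pKd/pKi,
    with model selection by a composite correlation-plus-error loss. A
    synthetic-complex generator plants interactions at known geometry so the
    whole pipeline is testable without external structure databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ranger,
    jsonlite,
    rlang,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
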