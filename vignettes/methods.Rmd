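---
title: "Interaction fingerprints, fragment descriptors and affinity models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprints, fragment descriptors and affinity models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plifr)
```

## The model

`plifr` scores protein–ligand binding affinity (pKd/pKi, i.e. −log10 of the
dissociation or inhibition constant in molar units) from two interpretable
descriptor families and a regressor.

**Interaction fingerprint.** For every binding-site residue, seven
interaction classes are evaluated pairwise against the ligand under
geometric rules: hydrophobic contact, face-to-face (F2F) and edge-to-face
(E2F) aromatic stacking, hydrogen bond accepted by the ligand
(protein donates), hydrogen bond donated by the ligand, and ionic contact
with the ligand negatively or positively charged. Counts are accumulated in
a fixed 20 × 7 matrix (the 20 standard amino acids, alphabetical by
three-letter code, × the seven classes in the order above) and flattened
row-major by amino acid into a 140-cell vector. Two distinct arginines each
hydrogen-bonding the ligand put a 2 in the `ARG_HBOND_ACC_LIG` cell. The
companion interaction-distance vector stores, per cell, the minimum
qualifying contact distance in Å (0 where the count is 0), giving the
280-feature `ifp+dist` set. The minimum was chosen over mean or sum because
the closest contact governs the energetics of an interaction; any of the
three would be a consistent convention.

**Fragment descriptors.** Ligands additionally contribute substructural
molecular fragment counts over the heavy-atom graph: all simple paths of
2–6 atoms ("sequences") and one "augmented atom" per heavy atom (the centre
plus the multiset of its bonded neighbours). Labels encode elements
(lower-case when aromatic) and bond orders (`-`, `=`, `#`, `:`); a
sequence's canonical label is the lexicographic minimum of its forward and
reverse renderings, and augmented labels sort their neighbour terms, so
counts are invariant to atom numbering. "Up to six atoms" is read as an
atom-count convention (paths of 2–6 atoms); single atoms are covered by the
augmented family. Counts, not binary presence, are kept: tree ensembles
exploit the magnitudes. The dictionary built on a training collection is the
lexicographically sorted union of both families; fragments unseen at
prediction time are dropped (and counted), because the feature space is
frozen when the model is trained.

**Regressors.** The random forest is a bagged ensemble of B regression
trees whose predictions are averaged; `max_features = "auto"` means all
features (the historic meaning of that setting in the scikit-learn 0.22
generation of tooling) and `"sqrt"` means ⌊√p⌋. The deep network is the
fixed stack input → Dense(400) → BN → ReLU → dropout → Dense(200) → BN →
ReLU → dropout → Dense(100) → BN → ReLU → dropout → Dense(1, linear),
trained with minibatch SGD (learning rate 0.001, inverse-time decay 1e−6
per update, momentum 0.9) on the mean squared error with an L2 penalty on
dense weights. After each epoch the validation set is scored with the
composite loss

LOSS = α (1 − PCC) + (1 − α) RMSE,

and the returned model is the epoch minimizing it; the composite loss is a
model-selection criterion, not the gradient objective. At α = 0 selection
reduces exactly to minimum validation RMSE; at α = 1 to maximum PCC. The
learnable-parameter count of the built network is
(d·400 + 400) + (400·200 + 200) + (200·100 + 100) + (100 + 1) + 4·(400 + 200 + 100)
— dense weights and biases plus four per-unit batch-norm terms (scale,
shift, running mean, running variance); the audit of the constructed
parameter arrays reproduces this closed form for any input dimension d.

**Evaluation.** RMSE, MAE, Pearson correlation (with a two-sided p-value
from the t-transform t = r√((N−2)/(1−r²))) and Spearman correlation
(Pearson on ranks). Correlations are reported as `NA` when undefined (N <
2, or constant predictions or labels) rather than coerced to a number. The
null baseline predicts the training-label mean for every test row; it is a
documented stand-in for an undescribed reference model and its PCC is
undefined by construction.

## Geometric rules and their defaults

| rule | default | notes |
|---|---|---|
| hydrophobic cutoff | 4.5 Å | C/S atom pairs |
| F2F centroid cutoff | 4.0 Å | ring centroid–centroid |
| F2F plane angle | ≤ 30° | angle between ring normals, folded to [0, 90°] |
| E2F centroid cutoff | 5.5 Å | |
| E2F plane angle | 60–90° | |
| H-bond D–A cutoff | 3.5 Å | donor–acceptor heavy-atom distance |
| H-bond D–H⋯A angle | ≥ 120° | applied only when the donor hydrogen exists |
| ionic cutoff | 4.0 Å | closest atoms of two opposite charged groups |

These are community-standard interaction-fingerprint thresholds; the exact
values used by proprietary profilers are not published, so all eight are
configurable (`geometric_rules()`), serialized to JSON, and recorded in the
detection output metadata.

## Event granularity and precedence

A record is one (residue, class, protein functional group) event: each
donor atom, each acceptor atom, each charged group (arginine's guanidinium
N trio, lysine's NZ, aspartate/glutamate's carboxylate O pair, a C-terminal
carboxylate) and each aromatic ring is one functional group, and a
residue's hydrophobic surface counts once. This keeps counts small and
interpretable while preserving the two-arginines → 2 semantics.

Two deliberate precedence rules prevent double counting:

- **Charged atoms are ionic-only.** Atoms inside a charged group are
  excluded from the donor and acceptor lists, so a salt bridge is one ionic
  record, not an ionic record plus a hydrogen bond at the same geometry.
  Consequently arginine's hydrogen-bond capacity is carried by its backbone
  amide nitrogen unless the guanidinium is neutralized in the input.
- **Stacking subsumes ring–ring hydrophobics.** A residue bearing an
  aromatic ring never counts ligand aromatic-ring atoms as hydrophobic
  partners; that contact surface is described by the F2F/E2F classes alone.
  The rule is structural (it depends only on typing, not on whether a
  stacking record fired), which makes every fingerprint cell monotone under
  shrinking any cutoff — an invariant the test suite checks. The cost is
  that a non-stacked graze between an aromatic residue and an aromatic
  ligand ring is not scored hydrophobic; for affinity features this
  trade-off favours stability.

Histidine is treated as aromatic and becomes cationic (and loses its
acceptor role) only under an explicit `protonated_his` flag, since
protonation states are not derivable from a plain PDB file.

## Structure handling

PDB and MOL2 parsing is delegated to `bio3d`, SDF to `ChemmineR` (with
V2000 `M CHG` formal charges recovered from the raw block, which ChemmineR
drops). Waters (HOH/WAT and variants) are removed by default without
touching other atoms; non-standard residues are retained but excluded from
featurization. Hydrogen handling is minimal by design: when requested, one
geometric hydrogen is placed on each donor N/O lacking one, 1.0 Å along the
direction away from the mean of its bonded heavy neighbours — enough to
apply the D–H⋯A angle test. Without hydrogens the H-bond rule is
distance-only. Bond-order correction and protonation-state prediction are
out of scope; an external preparation tool can be used upstream. Ligand
aromaticity is taken from file flags (`ar` bond types, order-4 SDF bonds)
and otherwise perceived from alternating Kekulé orders on 5/6-rings of C/N.
Disconnected ligands keep their largest fragment with a warning.

Dataset curation mirrors standard practice for affinity corpora: a strict
resolution filter (< 2.5 Å; structures without a resolution, e.g. NMR,
pass only under an explicit flag since they form a separate evaluation),
Kd/Ki-only labels (IC50 excluded), order-preserving removal of test-set
overlap from the training ids, and seeded 80:20 train/validation splits
(the canonical seed table 1…6 gives six reproducible subsets).

## Feature scaling

Forests consume the raw counts/distances. For the network, features are
standardized to train-set mean and unit variance and the constants are
stored with the model; SGD on mixed count (0–10) and distance (0–5.5 Å)
scales does not converge reliably without it. This is the package's own
choice where the upstream protocol is silent.

## What the synthetic generator does and does not emulate

`make_toy_complex()` places idealized residue templates (no rotamer
library, partial side chains) so that the interacting functional group sits
at an exact requested distance with rule-compliant angles, on one of six
orthogonal rays; ligand probe groups (ethane, benzene, carbonyl, hydroxyl,
carboxylate, methylammonium) attach to a central scaffold carbon so the
molecule stays connected, and decoy residues are placed ≥ 12 Å out. The 90°
ray separation guarantees every cross-plant protein–ligand distance exceeds
all cutoffs, so the ground-truth fingerprint implied by the specification
is exact — which is what makes the planted-recovery and brute-force-oracle
properties sharp tests of the detector.

What this does **not** emulate: real binding-site packing (many residues
engaging the same ligand atoms), conformational strain, water-mediated or
metal-coordination contacts, and chemically realistic torsions — the
scaffold "bonds" are geometric, not physical. Passing the fixture suite
therefore demonstrates the correctness of the geometry, typing and counting
machinery, not predictive performance on crystal structures.

`make_synthetic_dataset()` draws Poisson(1) counts (and uniform 2.5–4.5 Å
distances where counts are positive) with labels `w·x + N(0, σ²)`, so
`Var(label) = Var(w·x) + σ²` by construction. It validates learners'
ability to recover a planted signal (the acceptance check uses n = 500,
σ = 0.1, a 3-unit weight on one cell, and requires held-out PCC ≥ 0.9); it
says nothing about the feature–affinity relationship in real data.

## Numerical choices

- Label sorting uses radix order (`method = "radix"`) everywhere a
  dictionary or name order matters, making results locale-independent.
- Ring normals come from the SVD of centred ring coordinates; plane angles
  are folded into [0, 90°]. Batch-norm uses ε = 1e−5 and running-statistics
  momentum 0.9; weights are He-initialized.
- Forest training is pinned to one thread with an explicit seed, making
  predictions bit-reproducible; all generator and split randomness runs in
  a private RNG stream that restores the caller's state.
- Training minibatches of fewer than two rows are skipped (batch
  normalization is undefined on them); non-finite validation loss aborts
  with diagnostics rather than returning a silently broken model.
- Degenerate inputs: constant training labels warn (forest) or yield `NA`
  correlations (evaluation); empty record sets produce all-zero vectors;
  splits that would leave an empty side are errors.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
100 planted complexes (≤ ~150 atoms each) for the detector oracle, 50
random molecular graphs (≤ 30 heavy atoms) for the fragment oracle, n = 500
synthetic rows for forest recovery, and ≤ 12-epoch network runs for the
selection-rule checks. These sizes were chosen so the full pipeline
exercises every code path in well under a minute per property while keeping
the statistical checks sharp.

## Known limitations

- Water-mediated and metal-coordination interactions, halogen bonds and
  cation–π contacts are not detected.
- Ligand donor/acceptor perception is heuristic (no implicit-hydrogen
  model); unusual valences may type conservatively.
- Aromaticity perception covers flagged bonds and Kekulé 6-rings; exotic
  fused heteroaromatics from flag-free files may be missed.
- The fragment dictionary depends on the training ligand collection; its
  size (2282 on the corpus the method was developed against) is not a
  constant of the method.
- Binding-pose generation (docking) is consumed, not produced.
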