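# plifr — interaction-fingerprint and fragment-based affinity scoring

`plifr` builds interpretable machine-learned scoring functions for
protein–ligand binding affinity. Instead of opaque 3D-grid or radial
featurizations, a complex is described by two human-readable descriptor
families:

1. **Per-residue interaction fingerprint (IFP).** Seven interaction classes
   — hydrophobic contact, face-to-face (F2F) and edge-to-face (E2F) aromatic
   stacking, hydrogen bonds accepted and donated by the ligand, and ionic
   contacts with the ligand negative or positive — are detected between each
   binding-site residue and the ligand under configurable geometric rules
   (distance cutoffs, ring-plane angles, D–H⋯A angles). Counts are folded
   into a fixed 20 amino acids × 7 classes = **140-cell** vector; if two
   arginines each hydrogen-bond the ligand, the `ARG_HBOND_ACC_LIG` cell is
   2. A companion **140-cell distance vector** stores the closest contact
   distance (Å) per occupied cell, giving 280 features in total.
2. **Substructural molecular fragments (SMF) of the ligand.** Counts of
   linear atom sequences of 2–6 heavy atoms (`C-C-O`, `c:c:c`, …) and of
   augmented atoms (an atom with its bonded neighbours, `C(-C)(-O)`), with
   aromaticity lower-cased and bond orders encoded in the labels. A fragment
   dictionary is frozen on the training set and ligands are vectorized
   against it.

Feature sets `ifp` (140), `ifp+dist` (280), `ifp+frag` (140 + dictionary)
and `ifp+dist+frag` feed two regressors of the experimental affinity
pKd/pKi = −log10 K:

- a **random forest**: B bagged trees T_b(X), prediction
  Ŷ = (1/B) Σ_b T_b(X), with B ∈ {100…500} and `max_features` ∈
  {auto = all, sqrt};
- a **deep network**: Dense 400 → 200 → 100 → 1 with batch normalization,
  ReLU and dropout per hidden block, SGD (lr 0.001, decay 1e−6, momentum
  0.9), with per-epoch model selection on the validation set by the
  composite loss

  **LOSS = α·(1 − PCC) + (1 − α)·RMSE**,  α ∈ [0, 1].

Models are compared by RMSE, MAE, Pearson (PCC, with a two-sided t-test
p-value) and Spearman correlations, against a mean-predictor null baseline.
A synthetic-complex generator plants interactions at exact geometry, so the
whole pipeline is testable offline; the dataset tooling (strict < 2.5 Å
resolution filter, Kd/Ki-only labels, overlap removal, seeded 80:20 splits)
supports curated corpora such as PDBbind when available.

## Worked example

```r
library(plifr)

# plant two interactions in a synthetic complex and profile it
spec <- plant_spec(data.frame(
  residue_name      = c("ARG",           "PHE"),
  interaction_class = c("IONIC_LIG_NEG", "AR_F2F"),
  distance          = c(3.2,             3.6)),
  decoys = 3, seed = 1)
toy <- make_toy_complex(spec, dir = "fixtures", id = "demo")
records <- detect_interactions(toy$protein, toy$ligand)
records
#>   residue_name chain resno interaction_class distance
#> 1          ARG     A     1     IONIC_LIG_NEG      3.2
#> 2          PHE     A     2            AR_F2F      3.6
ifp <- build_ifp(records)
ifp[ifp > 0]
#> ARG_IONIC_LIG_NEG        PHE_AR_F2F
#>                 1                 1
```

The detector recovered exactly the planted salt bridge (arginine
guanidinium to a carboxylate oxygen at 3.2 Å) and the parallel stack
(phenylalanine ring centroid 3.6 Å from the ligand ring); the three decoy
residues, placed beyond every cutoff, contribute nothing.

```r
# regression on synthetic data: affinity = 3 * first-cell count + noise
w <- numeric(140); w[1] <- 3
ds <- make_synthetic_dataset(500, weights = w, sigma = 0.1, seed = 42)
sp <- split_dataset(ds, ratio = 0.8, seed = 1)
model <- train_rf(sp$train, rf_config(n_estimators = 100, seed = 1))
evaluate(model, sp$valid)
#> n = 100  RMSE = 0.0955  MAE = 0.0756  PCC = 0.9995 (p = 5.06e-147)  Sp = 0.9011
baseline_null(sp$train, sp$valid)
#> n = 100  RMSE = 2.8919  MAE = 2.1991  PCC = NA (p = NA)  Sp = NA
```

The forest recovers the planted linear signal almost perfectly (held-out
RMSE ≈ the noise level 0.1, PCC > 0.99), while the label-mean null model
explains nothing — the gap is what the features contribute.

## Command line

A thin wrapper over the same functions ships in `inst/cli/plif.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/plif.R", package = "plifr"))')" \
    fixtures --seed 5 --n 8 --out demo_fixtures
... featurize --index demo_fixtures/index.csv --features ifp+dist --out feats.csv
... build-dict --index demo_fixtures/index.csv --out dict.json
... train --index demo_fixtures/index.csv --features ifp+frag --dict dict.json --seed 2 --out model.rds
... evaluate --model model.rds --index demo_fixtures/index.csv --dict dict.json --out report.json
... profile --protein demo_fixtures/c01.pdb --ligand demo_fixtures/c01.mol2 --out c01.tsv
```

`profile` emits the per-complex interaction table (residue, class,
distance) used to compare e.g. docked against crystal poses residue by
residue.

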