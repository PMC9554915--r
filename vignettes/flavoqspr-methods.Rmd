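---
title: "Predicting flavoprotein redox potential from structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting flavoprotein redox potential from structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flavoproteins carry a noncovalently bound flavin cofactor (FMN or FAD)
whose midpoint redox potential E\_m — the average of the two one-electron
potentials, in mV — is tuned over hundreds of millivolts by the protein
matrix around the isoalloxazine ring. Measuring E\_m is slow;
physics-based predictions (QM/MM, Poisson–Boltzmann) are accurate but
expensive. `flavoqspr` implements a quantitative structure–property
(QSPR) alternative: descriptors of the protein environment are extracted
automatically from a PDB file, and regression models map them to E\_m.
Only protein amino-acid properties enter the descriptors; the cofactor
coordinates serve purely as geometric reference points, so the same
machinery transfers to other cofactor families.

## The descriptor vector

Each record yields 246 named descriptors:

* **Region descriptors, 3 × 55.** A fixed 55-value schema — 20
  residue-type counts, 11 class counts (total, polar, apolar, charged,
  positive, negative, hydrophobic, aromatic, small, H-bond donor and
  acceptor residues), 8 physicochemical property sums and their 8 means,
  4 side-chain element-count sums (N, O, C, S; e.g. `"Bar.nNats in side
  chain"`), and 4 derived counts (net formal charge, aromatic-residue
  side-chain atoms, H-bond donor and acceptor atoms) — evaluated at three
  spatial scopes: the whole chain owning the flavin (`Protein.<X>`), a
  sphere of radius r1 around the barycenter of the isoalloxazine ring
  (`Bar.<X>`), and the union of spheres of radius r2 around each ring
  atom (`Ring.<X>`). A residue belongs to a region when **any** of its
  non-hydrogen atoms lies inside; side-chain contacts drive
  flavin–protein interactions, so Cα-only membership would be too
  coarse. The sphere scopes take residues from the whole structure,
  while the protein scope and the sequence descriptors use the owning
  chain, identified as the chain with the smallest any-atom distance to
  the ring barycenter.
* **Ring-proximity atom counts, 3.** Protein N, O and C atoms within r2
  of any ring atom, each atom counted once.
* **N5-environment descriptors, 2 × 28.** The flavin N5 changes
  protonation state upon reduction, so its nearest residue matters: a
  20-value identity indicator plus the 8 property values for the nearest
  residue (`N5_nearest_<X>`), and identity counts plus property sums over
  that residue and its two sequence neighbours (`Around_N5.<X>`; a
  chain-terminal nearest residue contributes only the neighbours that
  exist). Nearest means minimum heavy-atom distance; exact ties go to the
  earlier chain, then the lower author residue number.
* **CTD sequence descriptors, 21.** Composition (3), transition (3) and
  distribution (15) of a three-class residue attribute along the owning
  chain's sequence. The full 21-value block corresponds to a single
  attribute; hydrophobicity (polar / neutral / hydrophobic, the standard
  Dubchak partition) is the default, with secondary-structure and
  solvent-accessibility partitions available. Distribution values are
  the sequence positions of the first, ⌈25 %⌉-th, ⌈50 %⌉-th, ⌈75 %⌉-th
  and last occurrence of each class, as a percentage of sequence length;
  an absent class contributes five zeros.
* **pH, 1.** The assay pH of the record; missing values are imputed from
  the training mean at fit time.

The barycenter is the unweighted mean of the 17 isoalloxazine ring-system
atoms (tricyclic core plus the C7M/C8M methyls and O2/O4 carbonyl
oxygens); FAD's `C4X`/`C5X` dictionary aliases are accepted for
`C4A`/`C5A`. For atoms with alternate locations only the
highest-occupancy altloc is kept (ties prefer `A`); hydrogens are parsed
but excluded from every distance computation and atom count, since X-ray
structures rarely resolve them and their inclusion would make counts
resolution-dependent. Waters and non-flavin hetero groups never enter any
descriptor. Only the first model of multi-model files is read. Structures
carrying several flavins contribute one row whose descriptors are the
element-wise mean over the per-site vectors.

Radii are scanned over the grid r1 = 8…16 Å by r2 = 3…6 Å (36
configurations), giving design matrices of n × 247 (246 descriptors plus
the E\_m label).

### The property table

The per-residue scales (volume, flexibility, hydrophobicity, steric
hindrance, polarity, isoelectric point, helix/sheet propensity) are
assembled from standard published sources — Zamyatnin volumes,
Bhaskaran–Ponnuswamy flexibility, Kyte–Doolittle hydropathy, Charton
steric parameter, Grantham polarity, free amino-acid pI and Chou–Fasman
propensities — and shipped as a plain-text TSV
(`inst/extdata/aa_properties.tsv`) together with side-chain element
counts, H-bond donor/acceptor atom counts and class flags. The schema,
not the particular scales, is the contract: a table with the same columns
can be swapped in via `aa_property_table(path)`. The derived atom-count
descriptors (aromatic atoms, H-bond donor/acceptor atoms) are computed
from this chemistry table rather than from the coordinates actually
present, so they do not depend on crystallographic completeness.
Histidine is deliberately counted as both positive (protonatable) and
aromatic; class counts may overlap, while polar/apolar partition the 20
residues exactly.

## Preprocessing and feature selection

All preprocessing is fitted on training rows only and applied to other
splits with the stored state, in a fixed order:

1. **pH imputation** by the training mean.
2. **Feature filtering**: zero-variance columns are dropped, then feature
   pairs are scanned in column order and the later column of any pair
   with |Pearson r| > 0.99 against a retained column is dropped
   (absolute correlation; a strongly anti-correlated duplicate is as
   redundant as a positive one). The scan order makes the filter
   deterministic and auditable — every dropped feature records its
   reason.
3. For the standardising estimators (LR, SVR, KNR, GPR): **centring and
   scaling** to training mean 0 / variance 1, followed by **elastic-net
   feature selection**, minimising
   \[(1/2n)\,\lVert y - Xw\rVert_2^2 + \alpha\rho\lVert w\rVert_1 +
   \tfrac{\alpha(1-\rho)}{2}\lVert w\rVert_2^2\]
   and keeping features with nonzero coefficients. The pair (α, ρ) is a
   hyperparameter searched jointly with the estimator grid over
   α ∈ {10, 100}, ρ ∈ {0.5, 0.75, 1}. The cost is fitted by coordinate
   descent (glmnet, whose objective matches this parameterisation with
   λ = α and mixing weight ρ); α = 0 reduces to ordinary least squares
   and selects everything, while an empty selection warns and falls back
   to all filtered features. Tree ensembles (RF, XGB) skip scaling and
   selection — they select features while growing their trees.

## Estimators, evaluation and comparison

Six regressors share one surface: linear regression (LR), support vector
regression (SVR, RBF kernel), k-nearest-neighbour regression (KNR),
Gaussian process regression (GPR, RBF kernel with a deterministic
median-heuristic bandwidth plus a noise-level grid), random forest (RF)
and gradient boosting (XGB). The tree models carry the max-depth grid
{3, 4, 5}; random forest exposes leaf count rather than depth, so depth d
maps to at most 2^d leaves (capped by the training size). KNR uses
uniform neighbour weighting with k ∈ {3, 5, 7, 9, 11}. Default grids are
documented in `estimator_spec()` and fully overridable; all other
hyperparameters stay at their library defaults.

Evaluation repeats R times (default 10): a random 80/20 split, an inner
5-fold cross-validated grid search minimising MAE on the 80 % (the full
preprocessing is refitted inside every fold, so no fold statistics
leak), a refit with the chosen hyperparameters on the whole training
part, and MAE, RMSE, R² (coefficient of determination; squared Pearson
correlation is a different quantity and deliberately not used) and
Spearman correlation on the held-out 20 %. The repeated-split protocol
is the default because it directly produces the mean ± sd summaries of
interest; a true outer 10-fold loop can be configured instead.
`radius_scan()` runs this at every (r1, r2) configuration and reports
the mean-MAE surface with its argmin.

Estimator pairs are compared by a two-sided Mann–Whitney U test on the
per-repetition metric samples (normal approximation with tie correction
and no continuity correction, so the p-value equals the from-definition
U-statistic computation; identical constant samples get p = 1), with
significance flagged at p < 0.05.

## Interpretation

`shap_explain()` produces additive per-feature attributions
φ with the local-accuracy contract: base value plus row sum equals the
model prediction for every sample. Three routes:

* **Linear models** — the closed form φ\_ij = w\_j (x\_ij − μ\_j) against
  the background mean μ.
* **Gradient-boosted trees** — exact path-dependent tree attributions
  computed in double precision from the dumped trees, with split
  comparisons performed in IEEE single precision to replicate the
  booster's branching exactly. The booster's built-in contribution
  predictor works in single precision, whose round-off at mV scale
  (~10⁻⁴) already exceeds the package's accuracy contract of 1e-4 mV;
  the double-precision implementation keeps the additivity residual
  near machine epsilon and agrees with the built-in predictor to within
  its float32 noise. Explained predictions for this route are the
  double-precision re-evaluation of the same trees.
* **Anything else** — Shapley values against a single mean-background
  reference: exact subset enumeration up to 12 features, seeded
  permutation sampling beyond (sampling error shrinks as 1/√nsim; the
  route is labelled in the explanation and not used where exactness is
  asserted).

`rank_features()` orders features by mean |φ| (ties by name), and
`final_model_explanation()` mirrors the end-of-study analysis: at the
best configuration (r1 = 13 Å, r2 = 3 Å for XGB), the model is tuned by
inner CV on all rows, refitted on the entire dataset and explained over
all rows, with CSV exports for the importance bar data and the
per-sample violin data.

## Synthetic fixtures: what they do and do not show

Because the curated experimental dataset is external, the package ships
two generators whose declared ground truth is exactly recoverable by the
pipeline — the central testing contract.

`generate_structure()` emits PDB text with an idealized planar
isoalloxazine (1.4 Å aromatic bonds, barycenter exactly at a chosen
point) and residues placed in declared distance bands from the
barycenter or a named ring atom. Each residue carries backbone N/CA/C/O
plus a minimal side-chain atom set with correct element counts, packed
within 0.75 Å of its anchor; bands are enforced with a 0.8 Å margin and
rejection sampling keeps all atoms ≥ 2 Å apart. This validates geometry,
counting and bookkeeping — it does not emulate real folds, secondary
structure, crystallographic noise or missing atoms, so passing tests
certify the extraction machinery, not biological realism.

`generate_planted_dataset()` emits feature tables named per the
246-descriptor contract with standard-normal features, planted exact
duplicates (r = 1) and one constant column to exercise the filter, a
mildly correlated pair (r ≈ 0.9) that must survive it, and labels
E\_m = μ + Xβ + ε with configurable sparse support. Coefficients are
rescaled so the label distribution matches the study's (mean −223 mV,
sd 109 mV) while the noise sd stays as requested (default 20 mV), which
makes the analytic MAE floor of an ideal predictor √(2/π)·σ ≈ 16 mV a
meaningful recovery target. Real descriptors are correlated, integer-
valued and heteroscedastic; the planted tables are none of these, so
recovery results bound what the pipeline can do under ideal conditions.

## Numerical choices and conventions

* Empty regions yield all-zero descriptors, means included — keeping the
  design matrix dense rather than introducing NaN.
* Distances are Euclidean in Å; no periodic images or symmetry mates.
* Design matrices round-trip through CSV bit-exactly (`%.17g`
  formatting).
* Correlation-filter and grid-search ties break by column/grid order;
  N5 ties by chain order then residue number.
* All randomness flows from explicit integer seeds; a fixed master seed
  reproduces splits, folds, fits and output files byte-for-byte.
* Validation problem sizes: oracle-equivalence checks run on ≥ 100
  random instances per operation; recovery experiments use the study's
  shape (141 × 246, 5 informative features) with 10 repeated splits; the
  XGB grid for the recovery experiment fixes the learning rate and
  round count at mid-grid values and scans depth {3, 4, 5}.

## Known limitations

* The numeric property scales are standard published ones, not the
  original study's exact table, so descriptor values (and any model
  trained on them) are not bit-comparable to that study; the schema and
  counts are.
* Which single attribute generated the study's 21 CTD features is not
  documented; hydrophobicity is the package default.
* Owning-chain assignment for a cofactor uses the nearest-chain rule; in
  interleaved multi-chain sites this is a heuristic.
* Covalently bound flavins are out of scope, as are structure-quality
  checks, resolution filtering and cofactor–protein interaction
  descriptors (H-bonds, stacking).
* Reproducing the study's reported performance (e.g. XGB MAE ≈ 36 mV)
  requires its 141 curated structures and labels, which are not bundled;
  the package validates against synthetic ground truth instead.
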