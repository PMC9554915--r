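# flavoqspr

Structure-based QSPR modelling of flavoprotein midpoint redox potential.

Flavoproteins bind an FMN or FAD cofactor whose midpoint redox potential
E_m (mV) is tuned by the surrounding protein matrix. `flavoqspr` predicts
E_m from a PDB structure alone: it locates the flavin's isoalloxazine
ring, extracts **246 named molecular descriptors** of the protein
environment, assembles labelled design matrices over a grid of cutoff
radii, trains and compares six regression models, and explains the
fitted model with additive (SHAP) feature attributions.

The descriptor vector combines:

- **3 × 55 region descriptors** — residue-type and class counts,
  physicochemical property sums/means (volume, flexibility,
  hydrophobicity, steric hindrance, …) and side-chain element counts,
  evaluated over the whole chain (`Protein.X`), a sphere of radius r1
  around the ring barycenter (`Bar.X`), and the union of spheres of
  radius r2 around each ring atom (`Ring.X`);
- **3 ring-proximity atom counts** (`Nitrogen_Around`, `Oxygen_Around`,
  `Carbon_Around`);
- **2 × 28 N5-environment descriptors** for the residue nearest the
  flavin N5 and its two sequence neighbours;
- **21 CTD descriptors** (composition/transition/distribution of a
  three-class hydrophobicity encoding along the sequence);
- the **assay pH**.

Radii are scanned over r1 = 8…16 Å × r2 = 3…6 Å (36 configurations).
Models (LR, SVR, KNR, GPR, RF, XGB) are evaluated by repeated 80/20
splits with an inner 5-fold grid search minimising MAE; the
standardising models are preceded by elastic-net feature selection

    (1/2n)·‖y − Xw‖² + αρ‖w‖₁ + α(1−ρ)/2·‖w‖₂²,  α ∈ {10,100}, ρ ∈ {0.5,0.75,1}

and estimator pairs are compared with a two-sided Mann–Whitney U test.
See `vignettes/flavoqspr-methods.Rmd` for the full methods account.

## Worked example

```r
library(flavoqspr)

# synthetic study: 8 PDB fixtures + record table (id, path, E_m, pH)
dir <- tempfile(); dir.create(dir)
records <- generate_study_records(n_structures = 8, dir = dir, seed = 42)

st <- parse_structure(records$pdb_path[1])
st
#> ProteinStructure <synthetic_01>: 11 standard residues in 1 chain(s); 1 hetero group(s)

locate_flavin_sites(st)[[1]]
#> FlavinSite FMN [A|901||FMN] chain A; barycenter (0.00, -0.00, 0.00) A

fv <- build_feature_vector(st, pH = records$pH[1], r1 = 13, r2 = 3)
round(fv[c("Bar.ResTotal", "Bar.nNats in side chain",
           "Nitrogen_Around", "Around_N5.Hydrophobicity", "pH")], 2)
#>             Bar.ResTotal  Bar.nNats in side chain          Nitrogen_Around
#>                      5.0                      2.0                      1.0
#> Around_N5.Hydrophobicity                       pH
#>                     -3.2                      6.8
```

`Bar.ResTotal = 5` says five residues have an atom within 13 Å of the
ring barycenter; two side-chain nitrogens sit among them, one protein
nitrogen lies within 3 Å of a ring atom, and the three residues around
the N5-nearest position have a summed Kyte–Doolittle hydrophobicity of
−3.2.

```r
dm <- build_design_matrix(records, r1 = 13, r2 = 3)   # 8 x 247
spec <- estimator_spec("RF", grid = data.frame(ntree = 100, max_depth = 3))
repeated_evaluation(dm, spec, n_repeats = 5, seed = 1)
#> ExperimentResult: RF (r1 = 13, r2 = 3), 5 repetitions
#>   MAE      50.96 +/- 19.97
#>   RMSE     54.03 +/- 21.81
#>   R2       -1.59 +/- 3.18
#>   SC        0.20 +/- 1.10
```

Eight toy records are far too few to learn from — the negative R² is the
honest result of a 2-row test split — but the object carries the full
per-repetition metric distributions used by `radius_scan()`,
`pairwise_model_comparison()` and the summary CSVs. On a real dataset the
same calls scan all 36 radius configurations and pick the best one per
estimator. Interpretation then follows with

```r
fin <- final_model_explanation(records, best_config = c(r1 = 13, r2 = 3))
head(fin$ranking)          # features by mean |SHAP| (mV)
export_shap(fin, "shap/")  # bar + violin plot data as CSV
```

A thin command-line wrapper (`inst/cli/flavoqspr.R`) exposes `extract`,
`scan`, `explain` and `simulate` subcommands over the same functions.

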