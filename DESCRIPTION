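Package: flavoqspr
Title: Structure-Based QSPR Modelling of Flavoprotein Midpoint Redox Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the midpoint redox potential (E_m, mV) of flavoproteins
    from their 3D structure. Parses PDB files, locates noncovalently bound
    FMN/FAD cofactors and their isoalloxazine ring, extracts 246 named
    molecular descriptors of the protein environment (region
    physicochemical counts and sums at three spatial scopes, N5-neighbour
    descriptors, sequence composition/transition/distribution features and
    assay pH), assembles design matrices over a grid of cutoff radii,
    trains and compares six regression models with nested hyperparameter
    search and elastic-net feature selection, and interprets fitted models
    through additive (SHAP) feature attributions. Includes synthetic
    structure and dataset generators for fully self-contained validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    glmnet,
    e1071,
    kernlab,
    caret,
    randomForest,
    xgboost,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
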