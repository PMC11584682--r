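Package: powdermix
Title: Hybrid Mixture Models for Pharmaceutical Powder Blend Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts particle size distribution, aspect-ratio distribution,
    true/bulk/tapped density and flow function coefficient (FFC) of
    pharmaceutical powder blends from raw-component characterisation and the
    formulation alone. Combines a probabilistic finite mixture model for
    number-based particle size and shape distributions (with
    Levenberg-Marquardt fitting of per-component shape correction factors),
    analytical density mixture rules, PCA compression of predicted
    distributions into regression features, machine-learning regressors with
    a flow-classification-aware response scaling, and model-based prediction
    intervals with leverage-corrected uncertainty estimates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    randomForest,
    xgboost,
    e1071,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
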