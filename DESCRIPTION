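Package: csadelr
Title: Immune-Inspired Hybrid Optimization of Logistic Regression Weights
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains binary logistic-regression classifiers without gradients
    by hybridising the clonal selection algorithm (CLONALG) with differential
    evolution (DE/rand/1/bin) local search over the clone pool. Candidate
    weight vectors (antibodies) are scored by metric-driven fitness functions
    (F1 score, Matthews correlation coefficient, inverse mean error, or
    inverse cross-entropy) under a fixed fitness-evaluation budget. Ships the
    two single-strategy ablations (classic CLONALG with inverse and pair-wise
    hyper-mutation; plain generational DE), loaders for four UCI clinical
    table dialects with listwise missing-value removal and fold-wise scaling,
    a stratified k-fold cross-validation harness with per-fold feature-weight
    export, seeded random-search hyperparameter tuning, an exact Wilcoxon
    signed-rank comparison, seeded synthetic logistic-data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
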