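Package: binderscreen
Title: Structure-Prediction-Based Filtering and Evaluation of Designed Protein Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating de novo designed protein minibinders with
    structure-prediction confidence metrics. Computes interface predicted
    aligned error (pAE_interaction), binder pLDDT, and Kabsch-superposition
    Calpha RMSD of predicted monomers and complexes against design models;
    applies two-stage threshold filters for folding (Type-I) and binding
    (Type-II) failures; selects designs by pareto fronts or top-fraction
    ranking; estimates SC50 affinity surrogates from yeast-display titration
    sequencing counts; accounts for design-pipeline compute efficiency; and
    orchestrates an inverse-folding/relax design cycle with pluggable stages.
    A synthetic-fixture generator provides toy complexes, controlled-RMSD
    perturbations, label-correlated confidence bundles, sort-count tables and
    full labelled benchmarks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
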