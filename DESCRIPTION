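Package: otsa
Title: Off-Target Safety Assessment by Ensemble Ligand-Based Target Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An ensemble framework for predicting off-target interactions of
    small molecules from 2-D structure alone. Six orthogonal ligand-centric
    target-prediction methods (similarity-active-subgraph mining, per-target
    QSAR classifiers, pharmacophore-descriptor similarity, the similarity
    ensemble approach with extreme-value E-value statistics, a machine-learning
    consensus, and a cross-pharmacology index) are aggregated into a normalized
    pseudo-score with a consensus filter, classified against training and
    in-vitro truth tables, optionally filtered by tissue expression, and
    summarized in a ranked off-target report. Includes a physicochemical
    promiscuity profiler (Ro5, 3/75 rule, pKa bins), a cohort-comparison
    statistics battery, and a synthetic chemogenomics generator with known
    ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    igraph,
    glmnet,
    randomForest,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
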