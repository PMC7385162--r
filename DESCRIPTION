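Package: cytopool
Title: Repeated Metaclustering and Ensemble Classification for Mass
    Cytometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multi-sample mass cytometry (CyTOF)
    cohorts built around repeated metaclustering: cells of every sample
    are clustered without downsampling, cluster centers are pooled and
    re-clustered many times into independent metaclustering solutions,
    and per-sample metacluster frequencies become engineered features.
    Unsupervised Laplacian-score feature selection removes redundant
    features within each solution; samples are classified by clinical
    phenotype with patient-level bootstrapped cross-validation and
    median-aggregated random-forest probabilities (AUROC); and
    cluster-level case-control significance is mapped onto single cells
    as a differentiation score over a 2-D embedding. Includes a
    synthetic-cohort generator with planted differential-abundance
    effects so the whole pipeline is testable without real data, plus a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    randomForest,
    rlang,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    optparse,
    pROC,
    Rtsne,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
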