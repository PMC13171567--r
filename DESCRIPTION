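Package: FGFRiScore
Title: Composite FGFR-Inhibitor Sensitivity Phenotyping and Leakage-Safe
    Transcriptomic Signature Modeling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs a reliability-weighted multi-drug composite
    sensitivity score for FGFR-inhibitor panels from single-concentration
    viability screens, predicts it from baseline transcriptomes under a
    group-aware nested cross-validation scheme with out-of-fold evaluation
    and a permutation null, derives an interpretable linear gene signature
    from fold-wise ridge coefficients, and projects that signature into
    expression cohorts with up-down, ssGSEA, rank-based and reduced-panel
    scoring plus cross-platform and proxy-label validation statistics. A
    synthetic-data generator emulates the statistical structure of the
    pharmacogenomic inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software, Pharmacogenomics, GeneExpression, Regression,
    CrossValidation
RoxygenNote: 7.3.3
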