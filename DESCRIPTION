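Package: ariprofiles
Title: Time-Specific Transcriptional Profiles of Acute Respiratory Illness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Extraction of time-specific transcriptional profiles of acute
    respiratory illness (ARI) from longitudinal nasal-mucosa expression data
    across four clinical groups (healthy, allergic rhinitis, asthma without
    exacerbation, asthma with exacerbation). Implements per-gene generalized
    least squares under a block-equicorrelated within-subject covariance with
    a consensus correlation, empirical-Bayes moderated t-statistics with
    Holm step-down selection of the ARI gene set, covariance-PCA signature
    extraction by first-principal-component loadings over time-point
    transitions, core/shared/distinct membership classification across
    groups, expression-kinetics scaling and average-linkage clustering, the
    a priori rule-based asthma-exacerbation adjudicator, and a synthetic
    longitudinal cohort generator with planted signatures for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, TimeCourse, DifferentialExpression,
    PrincipalComponent, Clustering
RoxygenNote: 7.3.3
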