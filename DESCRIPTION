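Package: momics
Title: Multi-Cohort Multi-Omics Modelling of Preterm Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-adjusted late integration of plasma cell-free RNA
    transcriptomics, targeted plasma proteomics and urine metabolomics for
    modelling pregnancy. Provides a synthetic multi-cohort data generator
    with planted signal for validation, structural quality control
    (modality complexity, cohort-signature and storage-time confound
    detection, correlation-network embedding), stacked per-modality
    estimation of gestational age at sampling, leave-one-out
    cross-validated preterm-birth classification with cohort-restricted
    feature selection and a weighted integration layer, linear mixed-effect
    feature screening with cohort as a random effect, correlated-module
    detection and hypergeometric pathway enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    ranger,
    lme4,
    pracma,
    igraph,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'momics-package.R'
    'classes.R'
    'feature_stats.R'
    'ga.R'
    'io.R'
    'ptb.R'
    'qc.R'
    'simulate.R'
    'utils.R'
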