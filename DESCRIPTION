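Package: occmap
Title: One-Class SVM Analysis of Regional Brain Morphometry with RBF
    Preimage Discriminative Maps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for one-class classification of case-control regional
    brain-morphometry feature tables. Implements the nu-one-class support
    vector machine and support vector data description (SVDD) with an RBF
    kernel, leave-pair-out cross-validation with nested kernel-parameter
    optimization, approximate RBF preimages of the learned boundary by
    fixed-point iteration, and matched-pair permutation inference for both
    the AUC and per-feature preimage map components. Includes a synthetic
    case-control cohort generator emulating cortical-surface morphometry
    tables (62 DKT regions x 5 surface measures plus global features), and
    readers/writers for the tab-separated tables produced by
    cortical-surface analysis pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
biocViews: Classification, StatisticalMethod, Neuroimaging
RoxygenNote: 7.3.3
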