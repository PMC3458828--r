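Package: connclass
Title: Classification of Whole-Brain Anatomical Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normalized, thresholded inter-regional anatomical
    connectivity matrices from probabilistic-tractography fiber counts,
    discriminates two subject groups (e.g. patients versus controls) from
    their whole-brain connectivity patterns via nested two-sample t-test
    feature selection, locally linear embedding and a Gaussian radial basis
    function support vector machine under leave-one-out cross-validation,
    assesses significance of the generalization rate by label-permutation
    testing, and extracts consensus discriminating connections with
    per-region weights. Includes a seeded synthetic-cohort generator that
    emulates the statistical structure of sparse nonnegative connectome
    data so the full pipeline can be exercised and validated without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
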