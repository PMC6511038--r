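Package: msnmap
Title: Morphometric Similarity Network Case-Control Analysis and Imaging
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks (MSN) from
    multi-feature regional MRI tables, performs multi-study case-control
    inference on global and regional network strength (covariate-adjusted
    linear models, Fisher's method meta-analysis, Benjamini-Hochberg FDR,
    hub-vulnerability correlation, region-class aggregation), relates the
    combined case-control map to regional gene expression by partial least
    squares with permutation testing of variance explained and bootstrap
    gene ranking, and tests PLS-derived gene sets by median-rank resampling,
    sign-concordance, and protein-interaction edge-count permutation.
    Includes a synthetic-data generator emulating the statistical structure
    of multi-cohort morphometric and regional-expression data, and a
    config-driven pipeline runner with reproducible seeds and manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
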