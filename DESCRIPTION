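Package: tilscope
Title: Whole-Slide Tumor-Infiltrating Lymphocyte Mapping, Spatial Statistics, and Outcome Association
Version: 0.1.0
Authors@R: person("tilscope", "developers", role = c("aut", "cre"), email = "maintainers@tilscope.dev")
Description: A fully automatic pipeline for quantifying tumor-infiltrating
    lymphocytes (TILs) on hematoxylin-eosin stained slide rasters: tissue
    field-of-view detection by CIELAB K-means at low resolution, lymphocyte
    segmentation with a small encoder-decoder convolutional network trained by
    cascade refinement, tiled global TIL maps and the TIL score
    (lymphocyte pixels over tissue pixels), affinity-propagation clustering of
    TIL patches with a 42-index internal cluster-validity feature set, and
    downstream association machinery (Spearman expression screens, mutation
    rank-sum tests, log-rank cutoff scans, K-means risk groups, Lasso-Cox
    selection). Ships a synthetic-slide and synthetic-cohort generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    survival,
    glmnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
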