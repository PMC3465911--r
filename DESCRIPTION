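Package: sitewise
Title: Batch-Effect-Aware Classification Analysis for Multi-Site Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifier-based analysis of heterogeneous multi-site datasets in
    the presence of batch effects, as encountered in multi-site neuroimaging
    cohorts. Provides a dissimilarity-space embedding of arbitrary data
    sources via farthest-first-traversal prototype selection, a two-level
    (site and subject) binary batch-effect encoding, cross-validation schemes
    that respect none, one, or both levels of the batch structure, an
    extremely-randomized-trees classification stage, and an intrinsic-prior
    Bayesian test of independence between predicted and true class labels
    suited to unbalanced two-class problems. A seeded generator of multi-site
    clustered datasets with controllable class signal, site effects, subject
    effects, and site-class confounding supports end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
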