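Package: gemcm
Title: Gene Expression Multifactorial Causal Modelling of Longitudinal Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a generative network model in which regional gene expression
    modulates the pairwise interactions among macroscopic brain factors
    (amyloid-beta, tau, cerebral blood flow, glucose metabolism, functional
    activity, grey-matter density), with inter-regional spreading of each
    factor over an anatomical connectome. Per-subject transcriptomic-imaging
    parameters are estimated by Bayesian sparse regression with a horseshoe
    prior, and analysed at the population level with a behavioural
    partial-least-squares pipeline (cross-block SVD, permutation tests,
    bootstrap ratios) linking parameters to cognitive decline. Includes a
    transcriptome preparation stage (Gaussian kernel spatial regression,
    leave-one-out probe selection, regional aggregation), cohort screening
    utilities (Mahalanobis outlier detection, trimmed-scores PCA imputation,
    cognitive slopes), and a synthetic-cohort generator for end-to-end
    validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
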