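Package: pregmix
Title: Non-Invasive Pregnancy Diagnosis in Gray Whales from Faecal
    Hormones and Drone Photogrammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to diagnose pregnancy in Pacific Coast Feeding Group
    gray whales from two non-invasive data streams: faecal progesterone
    metabolite (fP4m) immunoassays and drone-based photogrammetric body
    widths. Provides quality control and annual aggregation of assay and
    morphometric records, two-component normal mixture models (univariate
    and bivariate) fitted by a compiled EM algorithm, a constrained
    non-parametric bootstrap with forced inclusion of known-pregnant
    records that yields per-whale pregnancy probabilities with confidence
    intervals, Monte Carlo propagation of photogrammetric uncertainty
    through ANOVA group comparisons summarized with highest posterior
    density intervals, confusion-matrix evaluation against whales of
    known reproductive status, and a synthetic-data generator emulating
    the population structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
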