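Package: arstrack
Title: Behavioural Segmentation of Argos Whale Tracks with Switching
    State-Space Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Argos satellite telemetry of marine
    mammals: simulation of ground-truthed switching first-difference
    correlated random walk (DCRW) tracks with class-dependent Argos
    observation errors, preprocessing (quality filtering, gap splitting),
    Bayesian fitting of a two-state hierarchical switching state-space
    model by Markov chain Monte Carlo, behavioural classification into
    transiting and area-restricted search (ARS), rule-based detection of
    departure from a residency region, Kaplan-Meier residency analysis,
    segmentation into ARS patches and migratory phases with minimum convex
    polygon patch metrics, circular statistics of migratory bearings,
    smooth models of daily ARS proportion against habitat covariates, and
    PCA plus Ward clustering of ARS patches into types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
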