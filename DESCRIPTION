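Package: peakpattern
Title: Multinomial Inference on the Spatial Patterning of Peaks in
    Statistical Parametric Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian and classical inference on the spatial distribution of
    supra-threshold local maxima ("events") in 3D statistical parametric maps
    over a pre-specified brain parcellation.  Under the Poisson clumping
    heuristic, high peaks of a null statistic field form a homogeneous Poisson
    process in resel space, so event counts conditioned on their total are
    multinomial with probabilities given by relative regional resel counts.
    The package estimates regional resel counts from standardized residual
    fields, detects and counts supra-threshold peaks, compares a uniform null
    against a Dirichlet alternative by exact model evidence (fixed effects),
    fits a hierarchical Dirichlet random-effects model by MCMC, computes
    multiplicity-penalised credible intervals on regional event propensities,
    and validates frequentist operating characteristics with a non-stationary
    null field simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
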