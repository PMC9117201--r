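Package: paleodive
Title: Spatially Standardised, Sampling-Corrected Fossil Diversity Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating diversity dynamics from fossil occurrence
    data while correcting for spatial and temporal sampling bias. Implements a
    spatial standardisation workflow (sliding windows, hexagonal binning,
    longitude-latitude clipping and minimum-spanning-tree trimming with
    diversity-extent diagnostics), a hierarchical Bayesian diversity estimator
    that models sampled richness as a binomial draw from unknown true
    diversity under time-variable Poisson preservation with optional
    gamma-distributed rate heterogeneity across lineages, a birth-death plus
    preservation simulator for validation, baseline diversity estimators
    (raw, range-through, coverage-based rarefaction, squares extrapolator),
    and abundance-corrected Forbes* turnover between adjacent time bins.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
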