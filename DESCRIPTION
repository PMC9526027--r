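Package: bmsom
Title: Biogeographic Multi-Species Occupancy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical multi-species occupancy models (MSOMs) for
    biogeographic-scale survey data. Pre-existing range information (range
    polygons, elevational limits, seasonal presence windows) enters the model
    as species-specific "range covariates" with hierarchical random slopes,
    and severely out-of-range species-site combinations can be removed a
    priori ("biogeographic clipping"). Includes a synthetic community
    simulator with known truth, construction of range covariates from planar
    range geometries, a marginalized-likelihood occupancy model fit by
    adaptive Hamiltonian Monte Carlo (No-U-Turn sampler with analytic
    gradients), convergence diagnostics (rank-normalized split R-hat,
    divergences, E-BFMI), approximate leave-one-out cross-validation by
    Pareto-smoothed importance sampling, a data-augmented baseline model with
    pseudospecies, and posterior prediction of occupancy surfaces and
    point-scale species richness including never-observed species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
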