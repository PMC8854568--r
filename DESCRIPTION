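Package: canopyphen
Title: Vertically Stratified Canopy Phenology from Terrestrial Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating plant area density (PAD) and plant area index
    (PAI) from terrestrial laser scanning (TLS) pulse records by voxel-based
    gap-fraction inversion, and for analysing the vertical stratification,
    forest-edge effects and seasonality of tropical forest canopies. Includes a
    ray-traced synthetic-forest simulator (voxelised PAD truth fields, TLS
    surveys, PAI panels, microclimate and rainfall series) so that every stage
    of the chain -- grid traversal, free-path-length attenuation estimation,
    digital terrain modelling, stratified PAI, asymptotic edge-gradient and
    hockey-stick breakpoint models, phenology mixed models with permutation
    envelopes, and dry-season classification -- is verifiable by parameter
    recovery without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
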