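Package: fdlandings
Title: Trait-Based Functional Diversity Analysis of Fisheries Landings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the functional trait diversity of fish
    assemblages reported in fisheries landings. Implements a 14-trait
    coding scheme (13 crisp traits plus a fuzzy-coded diet trait, 76
    modalities across four ecosystem functions), a Gower-type mixed
    trait distance, principal coordinates and fuzzy correspondence
    analyses of trait space, landings-weighted functional diversity
    metrics (FRic, FEve, FDiv, FDis), and trait-profile permutation
    null models for comparing fleets and decades. Includes a synthetic
    landings generator emulating multi-decadal, two-fleet, strongly
    skewed landings records for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ade4,
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
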