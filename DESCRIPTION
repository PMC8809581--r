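Package: flocknet
Title: Social Network Analysis of Mixed-Species Bird Flocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing animal social networks from
    gambit-of-the-group flock observations. Converts flock sighting records
    into group-by-individual matrices, computes Simple Ratio Index (SRI)
    association networks, detects communities by iterative removal of
    high-betweenness edges with modularity optimisation, and quantifies
    species and community assortativity. Inference is by datastream
    (group-membership-swap) permutation nulls using the serial method,
    node-label permutations, and a flock bootstrap with the r_community
    robustness coefficient. Includes a synthetic flock-observation generator
    with planted community structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
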