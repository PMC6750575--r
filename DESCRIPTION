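Package: riverpg
Title: Microsatellite Population Genetics for River-Networked Mosquito Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for diploid microsatellite population-genetic analysis of
    Aedes aegypti (and similar) populations sampled across river-connected
    settlements: observed/expected heterozygosity and inbreeding coefficients,
    exact Hardy-Weinberg tests (full enumeration and Markov chain Monte Carlo)
    with Sidak family-wise correction, pairwise Weir-Cockerham F_ST with
    permutation significance, four-level hierarchical AMOVA, Mantel tests of
    isolation by distance under Euclidean, fluvial-path, shortest-path and
    transport-based propagule-pressure distance models, and Bayesian admixture
    clustering with Evanno Delta-K model choice. Includes seed-deterministic
    synthetic-data generators (Balding-Nichols differentiation, inbreeding
    mixtures, admixed populations, fragment-size panels and a hub-and-spoke
    transport network) so every stage of the pipeline can be validated by
    parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
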