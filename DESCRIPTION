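Package: seirtrees
Title: SEIR Epidemics on Clustered Contact Networks and Their Transmission Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for asking whether clustering in a contact
    network leaves a detectable signal in epidemic transmission trees.
    Generates Bernoulli and approximate power-law random networks, rewires
    them to high or low clustering by a Metropolis-Hastings sampler over
    degree-preserving double-edge swaps targeting a geometrically weighted
    edgewise-shared-partner (gwesp) exponential random graph density, runs
    paired event-driven stochastic SEIR epidemics with gamma-distributed
    latent and infectious periods, extracts timed transmission trees, and
    compares distributions of epidemic-curve and tree-shape summary
    statistics (final size, epidemic length, peak prevalence and timing,
    branch lengths, secondary infections, infective descendants, cherries)
    between the high- and low-clustering arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
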