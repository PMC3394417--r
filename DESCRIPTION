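Package: cmrf
Title: Comparative Markov Random Field Analysis of Differential Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies primarily differentially regulated genes in two-group
    perturbation experiments. Control and non-control expression data from two
    sample groups are combined with a directed gene interaction network through
    a Bayesian Markov random field prior over pairwise interaction variables, a
    hierarchical Gaussian marginal likelihood, and an alternating optimization
    of iterated conditional modes and differential evolution. Ships simulators
    for network-propagated perturbation benchmarks with known ground truth,
    ranking and sensitivity utilities, and a permutation-based null analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
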