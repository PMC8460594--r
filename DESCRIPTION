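Package: treeurn
Title: Urn Models for Cherry and Pitchfork Counts in Random Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the Yule-Harding-Kingman (YHK) and proportional to
    distinguishable arrangements (PDA) tree-growth processes on rooted and
    unrooted phylogenetic trees, classifies tree edges into the six types
    whose censuses evolve as a balanced Polya urn with (possibly negative)
    integer replacement matrices, and computes the joint law of the cherry
    and pitchfork counts three ways: analytically from the spectral
    decomposition of the replacement matrix (strong-law limits and central
    limit theorem covariances), exactly by dynamic programming over the
    edge-type Markov chain in arbitrary-precision rational arithmetic, and
    empirically by seeded Monte Carlo simulation.  Includes a command-line
    interface for simulation, edge-type statistics, analytic limits, exact
    moments, and convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
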