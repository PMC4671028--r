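Package: neonet
Title: Graph-Theoretic Analysis of Neonatal Resting-State Functional Networks
Version: 0.1.0
Authors@R:
    person("Developing Connectome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of resting-state functional connectomes in
    newborns: ROI time-series cleaning (motion censoring, nuisance regression,
    band-pass by projection), Pearson connectivity matrices, binary graph
    construction under correlation, degree, and cost thresholding, small-world
    and cost-efficiency metrics against degree-preserving null ensembles,
    cumulative degree-distribution model selection by AIC (power law,
    exponential, exponentially truncated power law), hub identification and
    Louvain community detection, and network-resilience simulations under
    random failure and targeted attack. Includes a synthetic cohort generator
    with planted modular small-world structure so the full pipeline is testable
    without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
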