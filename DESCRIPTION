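Package: moranet
Title: Moran Invasion Processes and Robustness Against Invasion on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Moran birth-death invasion process on undirected
    networks, estimates fixation probability functions by the embedded
    Markov chain (EMC) Monte Carlo method or by exact solution of the
    absorbing-chain linear system, and computes a robustness-against-invasion
    index that locates a network's fixation function between the isothermal
    (complete-graph) baseline and the complete-bipartite amplifier limit.
    Ships deterministic hierarchical, spatial toy-worm and preferential
    attachment benchmark generators, degree-preserving randomisation
    ensembles, degree/temperature/small-world/power-law statistics,
    modularity and Infomap description length, box-counting fractal
    dimension and Rent's-rule exponents, and rank-correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
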