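Package: dualnet
Title: Dual-Connectivity Assessment of Network Robustness Under Attack
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates sequential node-removal attacks (random failure,
    degree-proportional targeted attack, random spreading) on undirected
    networks and jointly tracks the connectivity of the surviving Active
    Network and of the removed Idle Network. Provides the paired attack
    efficiencies (E_A, E_I), the weighted robustness metric R_N(alpha),
    crossover analysis between attack strategies, generators for prototype
    networks (periodic square lattices, Tokunaga self-similar trees,
    Barabasi-Albert scale-free graphs, surrogate point-to-point airline
    networks), ensemble experiment runners, and a small command-line
    interface. The largest-cluster trajectories are computed with an
    incremental union-find tracker so that full-horizon attacks on
    10,000-node networks take milliseconds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
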