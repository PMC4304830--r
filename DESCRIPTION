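Package: grndesign
Title: Evolutionary Design and Robustness Analysis of Gene Regulatory Network Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the topological robustness of gene
    regulatory networks and for evolving robust network architectures in
    silico. Networks are signed adjacency matrices simulated with a
    Hill-kinetics ordinary differential equation model; robustness is the
    Monte Carlo fraction of uniformly sampled kinetic-parameter sets under
    which a target dynamic behavior (sustained oscillation or bistability)
    is preserved. Includes a genetic algorithm over topology matrices with
    tournament selection, matrix crossover and mutation, a two-stage
    fitness-approximation evaluator and an archive of evaluated topologies,
    plus phase-response-curve analysis, complexity metrics and comparison
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
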