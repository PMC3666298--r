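Package: isledock
Title: Island-Model Lamarckian Genetic Algorithm for Protein-Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible-ligand, rigid-receptor docking with an island-model
    Lamarckian genetic algorithm. Subpopulations evolve asynchronously on
    simulated heterogeneous workers, exchange elite chromosomes when their
    completion times align, and synchronize across island groups at a fixed
    migration interval. Includes an AutoDock4-style pairwise empirical energy
    function evaluated without grid maps, Solis-Wets local search with
    Lamarckian write-back, a pattern-reduction operator that freezes converged
    gene loci, differential-evolution and particle-swarm island baselines, a
    PDBQT reader/writer for a documented subset, and a toy-system generator
    with a planted optimum for reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
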