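Package: grnmod
Title: Evolution of Modularity in Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of modularity in Wagner-type gene
    regulatory networks and analyses directed-network modularity. Provides a
    discrete synchronous threshold model of developmental dynamics with
    attractor (gene activity phenotype) detection, a population-level
    evolutionary engine with roulette-wheel selection and density-biased
    mutation, Leicht-Newman spectral modularity optimization for directed
    graphs, degree-preserving edge-switching null models with normalized
    (z-score) modularity, and scenario runners for multi-phenotype selection
    experiments, parameter sweeps and empirical edge-list analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
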