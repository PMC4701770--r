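Package: matenet
Title: Assortative Mating Metrics for Bipartite Sexual Networks
Version: 0.1.0
Authors@R:
    person("Sam", "Whitlock", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify assortative mating by mating success on
    bipartite sexual networks (males x females, edges = copulations).
    Implements Newman's degree assortativity in directed and undirected
    form, the NODF nestedness metric based on percentage overlap and
    decreasing fill, and the sperm competition intensity correlation
    (SCIC) built on the harmonic mean of partner mating success under a
    fair-raffle paternity model. Includes the decomposition of the
    Bateman gradient into mating-success and sperm-competition
    components, a uniform generator of random mating networks with
    fixed size, sex ratio and mating density in which every individual
    mates at least once, and a sensitivity study of all metrics across
    population size, sex ratio and mating density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
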