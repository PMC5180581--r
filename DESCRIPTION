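Package: grnswarm
Title: Evolutionary Simulation of Genome-Encoded Regulatory-Network Robot Controllers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An artificial-life platform in which swarms of digital organisms
    ("robots") forage, prey, aggregate and replicate on a toroidal grid with
    typed, regrowing food sources and seasonal energy costs. Each organism is
    steered either by an artificial genome whose environment-activated gene
    regulatory subnetwork is instantiated as interacting agents with decaying
    concentrations, or by a fixed-topology neural-network baseline with
    per-edge reinforcement learning and performance-triggered edge zeroing.
    Provides seeded, reproducible single runs and replicated two-arm
    experiments, per-window behavioural metrics (prey and aggregation
    frequency, neighbour statistics, neighbour-density maps), and the
    food-remaining-at-extinction group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
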