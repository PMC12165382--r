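Package: repliforge
Title: Stochastic Whole-Genome DNA Replication Simulation and Origin
    Firing-Rate Inference for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven stochastic model of S-phase DNA replication in
    Saccharomyces cerevisiae in which replication origins compete to
    associate with a limited, recycling pool of firing factors. Provides a
    kinetic Monte Carlo simulator of origin firing, bidirectional fork
    progression, passive replication and factor recycling on a 1-kb genome
    grid; readers for OriDB-style origin catalogs and replication-timing
    profiles; iterative fitting of per-origin firing rates to timing data;
    and population-level replication statistics including timing mean and
    variability, S-phase length, inter-origin distances, origin efficiency,
    replication fork directionality, replicon lengths, fork and factor time
    courses, and firing-factor titration sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
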