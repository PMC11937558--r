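Package: equiprox
Title: Proximity-Sensor Analysis of Equine Social Spacing and Agonistic Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for 1 Hz dyadic distance streams from
    ultra-wideband proximity sensors on group-housed horses. Cleans raw
    sensor channels (out-of-range and sub-5 cm artifacts, frozen segments,
    feeder-forced proximity), averages technical replicates, and quantifies
    absolute and relative interindividual distances, time spent in proximity
    bins, closest and least frequent associates, median-threshold social
    networks with degree, betweenness and closeness centrality, and
    rule-based agonistic approach/retreat events with per-horse-hour rates.
    Includes an attraction-repulsion agent-based herd simulator with
    scripted agonistic episodes and a sensor-noise model that provides
    ground truth for every stage, plus a Monte-Carlo Fisher-Pitman
    permutation test and Spearman rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
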