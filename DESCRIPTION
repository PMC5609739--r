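Package: dapgminer
Title: Protein Complex Prediction by Mining Overlapping Dense Subgraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein complexes from protein-protein interaction
    (PPI) networks by transforming the network into a directed acyclic
    prefix graph (DAPG) and greedily mining overlapping dense subgraphs
    with configurable traveler and objective functions. Includes the full
    evaluation suite used in complex-prediction benchmarks (overlap score,
    FMeasure, clustering accuracy, maximum matching ratio, reference
    filtering, perfect-match counting, cumulative overlap histograms),
    seeded synthetic network generators with planted ground-truth
    complexes, and an offline screen that corroborates false-positive
    predictions against local PDB chain-map snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
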