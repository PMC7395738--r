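Package: codegnet
Title: Cross-Study Co-Deregulated Gene Meta-Analysis and Upstream Regulator
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for multi-study differential expression
    meta-analysis. Computes Characteristic Direction differential expression
    signatures per case/control study, derives cross-study consensus
    co-deregulated genes (co-DEGs), performs over-representation analysis with
    rank-deviation combined scores, infers upstream transcription-factor and
    kinase regulatory networks over a background protein-protein interaction
    network with k-core/betweenness hub detection, and ranks drug perturbation
    signatures by a signed connectivity score for repurposing candidates.
    Includes a seeded synthetic-data generator with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
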