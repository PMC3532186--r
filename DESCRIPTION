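Package: cappic
Title: Cluster-Based Confidence Assessment of Protein-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Topology-only confidence scoring for interaction networks.
    Interactions are clustered by applying Markov clustering (MCL) to the
    line graph of the network, each protein receives a hypergeometric
    fidelity to every cluster, and each interaction is scored by the
    product of its two endpoint fidelities. The clustering granularity
    (MCL inflation) is selected automatically by partially rewiring the
    network in a degree-preserving manner and minimising the one-sided
    Wilcoxon rank-sum P-value separating original from rewired link
    scores. Includes a planted-module synthetic network generator, a
    degree-preserving rewiring null model, a common-neighbour
    hypergeometric baseline scorer, and a repeated-ROC benchmarking
    harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
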