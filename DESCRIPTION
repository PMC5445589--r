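Package: subnetbench
Title: Synthetic Gold Standards and Benchmarking for De Novo Pathway Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates bias-free synthetic gold standards for de novo pathway
    (active subnetwork) enrichment: foreground/background node splits of
    controllable sparsity embedded in a protein-protein interaction network
    (seed-and-extend and average-distance-k selection), simulated case/control
    expression profiles of controllable signal strength (varying-mean and
    varying-variance Gaussian models), sparsity metrics for foreground sets,
    and a precision/recall/F-measure evaluation harness that sweeps signal
    strength, sparsity and method-internal parameters for any subnetwork
    extraction method plugged in through a simple adapter contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
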