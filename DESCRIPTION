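Package: amendr
Title: Active Module Identification on Multiplex-Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Network propagation and active-module identification on
    multiplex-heterogeneous graphs. Implements random walk with restart with
    per-block column normalization and layer/component crosstalk parameters,
    biased random walks driven by node attributes or nodes of interest,
    degree-bias adjustment (stationary-distribution scaling, bistochastic
    scaling via iterative proportional fitting, inflation-normalization, and
    penalized degree normalization), multiplex layer aggregation, and an
    iterative diffuse-filter-subgraph search that returns a connected module
    enriched for large experimental values. Includes synthetic graph and seed
    generators, benchmarking utilities (cross-validated node ranking,
    score-degree correlation, biased-walk impact metrics), and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
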