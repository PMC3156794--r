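Package: dc3net
Title: Differential Gene Network Inference with the C3NET Mutual-Information Core
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers direct-interaction gene networks from two gene-expression
    conditions (for example tumor and normal) and contrasts them. Each
    condition's network is inferred with the conservative causal core rule
    (every gene keeps only its maximum significant mutual-information
    partner), mutual information is estimated with a copula-transformed
    parametric Gaussian estimator, and a rank/MI decision filter then splits
    the inferred interactions into a test-specific network, a
    control-specific network and a common network. Includes subnetwork
    utilities (gene-list filters, hubs, top edges, connected components),
    a two-condition synthetic-data generator with known ground truth, and
    recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
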