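Package: contrastnet
Title: Contrast Subgraph Mining for Comparing Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts contrast subgraphs, node sets densely connected in one
    network and sparsely connected in another network defined over the same
    nodes, via greedy peeling on the signed difference graph. Includes
    construction of complete weighted coexpression networks from expression
    matrices (Spearman correlation or proportionality with WGCNA-style soft
    thresholding), downstream statistics for comparing the extracted modules
    (degree-distribution tests, set-overlap tests, gene-set enrichment,
    fold-change calls, mRNA-protein agreement), and seeded generators of
    planted differential modules for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
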