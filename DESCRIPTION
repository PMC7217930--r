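Package: reponet
Title: Network-Medicine Drug Repositioning from Evidence-Filtered
    Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds evidence-filtered gene-disease, drug-disease and
    drug-gene knowledge networks from tabular association records,
    detects network modules by Louvain modularity optimization,
    quantifies disease-pair overlap with exact hypergeometric tests,
    performs self-contained gene-set over-representation with a
    permutation-based combined score, computes co-expression module
    eigengenes and kME-based hub genes, and runs a multi-filter drug
    repositioning cascade that prioritizes drugs targeting a single
    disease-exclusive co-expressed hub gene. Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is
    testable end to end.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
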