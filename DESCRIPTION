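Package: socioscope
Title: Social Association and Multimodal Communication Network Analysis
    for Group-Living Equids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nearest-neighbour association networks from scan-sample
    records of stable social groups (harems), computes simple ratio indices
    (SRI) of dyadic association together with degree, individual and
    group-level coefficients of variation and network density, and tests for
    preferred associates with permutation null models.  Constructs multimodal
    signal co-occurrence networks from coded interaction postures, with a
    rare-component cleaning filter, component diversity and its jackknife
    subsampling null, density adjusted for mutually exclusive morphological
    states with a node-subsampling null, and fast-greedy module detection.
    Computes scan- and focal-based activity budgets, step rates and active
    interaction rates.  Includes synthetic-data generators with planted
    ground truth so every stage of the pipeline can be validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
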