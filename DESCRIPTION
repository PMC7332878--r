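Package: syndromine
Title: Literature Mining of Syndrome-Associated Genes by Network
    Decomposition and Symptom Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-track text-mining pipeline that identifies genes
    associated with traditional-Chinese-medicine syndromes from abstract
    corpora. The decomposition track performs dictionary-based gene named
    entity recognition, distant-supervision multi-instance relation
    extraction against a protein-interaction knowledge base, co-occurrence
    network construction, Louvain community decomposition, and composite
    centrality scoring (the CMI and gene-weight ranking). The combination
    track counts per-symptom gene hits, enumerates symptom combinations
    from a main / Qi-deficiency / blood-stasis classification, and
    intersects gene sets across combinations. Results from both tracks
    are matched per syndrome and intersected across diseases, with
    optional hypergeometric over-representation analysis. A
    synthetic-corpus generator with planted relations makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
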