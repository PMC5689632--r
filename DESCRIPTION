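Package: mirec
Title: Personalized Recommendation of Disease-Associated miRNAs on
    Heterogeneous Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate microRNAs for human diseases by fusing
    disease semantic similarity computed over a MeSH-style directed acyclic
    graph, curated miRNA functional similarity, and Gaussian
    interaction-profile kernel similarity derived from a known bipartite
    miRNA-disease association network. A personalized-recommendation scoring
    scheme combines TF-IDF-like rating matrices with similarity projections
    of the association network into a single prediction score per
    disease-miRNA pair. Includes a global leave-one-out cross-validation
    harness with ROC/AUC summaries, top-k reference-set validation
    protocols (including scoring of diseases with no known associations),
    and a synthetic planted-block network generator so the whole pipeline
    is testable without external database downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
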