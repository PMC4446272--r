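Package: trilayer
Title: Three-Layered Network Integration of Transcriptomics and Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multilayer enrichment-map style networks linking enriched
    biological processes, transcription-factor regulons and physiological
    parameters through their shared gene sets. Provides a moderated two-sample
    t-test for two-group differential expression, preranked gene set enrichment
    with a seeded gene-sampling permutation null, hypergeometric regulon
    enrichment with activation z-scores and identical-target clustering,
    Spearman correlation of per-animal phenotypes with expression, gene-set
    overlap network assembly with layer-specific similarity cutoffs, network
    topology statistics, and a synthetic-study generator with a truth manifest
    for end-to-end validation. Tibble-first interfaces with broom-style tidiers
    and ggplot2 autoplot methods.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
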