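Package: aquacomm
Title: Community Assembly, Source Tracking and Co-Occurrence Networks for
    Size-Fractionated Groundwater Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing microbial communities from soil via seepage
    into fractured-rock groundwater. Merges 0.1 and 0.2 micrometre
    filter-fraction amplicon communities into whole-community profiles using
    16S rRNA gene qPCR weights, quantifies taxon mobilization between
    compartments (enrichment factors, shared OTU fractions), infers
    community-assembly processes from phylogenetic and taxonomic null models
    (beta-nearest-taxon index and the rescaled Raup-Crick index on
    Bray-Curtis distance), profiles hydrochemical preferences of taxa
    (Spearman correlation profiles, UPGMA clustering, PCA), and reconstructs
    sparse positive co-occurrence networks from centred-log-ratio transformed
    counts via Meinshausen-Buhlmann neighborhood selection with
    stability-based (StARS) edge confidence. A synthetic-data generator
    produces complete datasets with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
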