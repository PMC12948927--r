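Package: slimediv
Title: Null-Model Beta Diversity and Succession Analysis for
    Hydrogen-Amended Aquifer Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the taxonomic succession of subsurface
    microbial communities exposed to dihydrogen, as in laboratory
    incubations of deep-aquifer formation water used for underground gas
    storage. Provides readers and writers for QIIME2-style ASV feature
    tables and study metadata, per-sample alpha diversity (richness,
    Stoddart/inverse Simpson, Shannon, Pielou), an incidence-based
    mock-community null model for pairwise between-experiment Jaccard
    beta diversity with z-score normalization, classification of
    convergence patterns over time, genus-level metabolic guild
    profiling with chord-diagram edge-list export, and a seeded
    synthetic-data generator that emulates multi-experiment ASV time
    series so the whole pipeline can be exercised without sequencing
    data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
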