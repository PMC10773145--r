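Package: linguomics
Title: Tongue-Coating Metaproteomics: Taxonomic Resolution, Host-Microbe
    Quantification and Gastric Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for tongue-coating
    metaproteomics of gastric cancer and non-cancer cohorts. Builds
    combined host plus metagenome-derived protein search databases with a
    two-step reduction from peptide-spectrum-match tables, performs
    in-silico tryptic digestion with missed-cleavage handling and
    peptide-centric taxonomic annotation under a narrowest/broadest
    branch rule, partitions protein quantification into human and
    microbial origins with sample quality control, summarises temporal
    stability of the tongue-coating proteome, runs differential protein
    and Fisher enrichment statistics, estimates per-species gastric
    cancer risk odds ratios, and trains a feature-selected stochastic
    gradient-boosted screening model. A synthetic-data generator with a
    ground-truth ledger emulates the study cohort designs so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
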