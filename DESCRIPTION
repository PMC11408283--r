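Package: cpipred
Title: Compound-Protein Interaction Prediction from Curated Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting compound-protein interactions (CPI) from
    multi-source bioactivity records. Provides curation rules for building an
    unbiased benchmark (potency thresholding at 10 uM, any-active label
    resolution, molecular-weight filtering, Tanimoto-based ligand deduplication
    and per-protein negative capping), a canonical-correlation negative screen,
    featurization by PCA-reduced circular fingerprints and averaged 3-mer CBOW
    protein embeddings, a fully connected neural classifier with grid search,
    threshold-free evaluation metrics, an applicability-domain analysis based
    on embedding distance to the training proteins, and a seeded synthetic
    benchmark generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
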