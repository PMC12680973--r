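Package: coembed
Title: Self-Supervised Multi-Modal Co-Embedding of Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates any number of proteomic data modalities -- weighted
    interaction networks (AP-MS, PL-MS, SEC-MS) featurized by node2vec, or
    precomputed per-protein feature tables such as image embeddings -- into a
    single unified protein embedding. A bank of per-modality encoders and
    decoders is trained with a cross-modal cosine reconstruction loss and a
    cross-modal triplet loss, so that every protein measured by at least one
    modality receives a latent coordinate. Includes the downstream evaluation
    statistics (top-fraction pair extraction, pairwise AUROC, Wilcoxon/BH term
    recovery), concatenation and standard-autoencoder baselines, proximity
    network thresholding with pluggable multiscale community detection and
    assembly scoring, and a synthetic-data generator with planted communities
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
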