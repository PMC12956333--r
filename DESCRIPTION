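Package: syncodon
Title: Synonym-Constrained Codon Language Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for codon-level language modeling of protein-coding DNA
    under a synonymous-codon constraint: a codon tokenizer and genetic-code
    utilities, an additive logit mask that restricts masked-codon prediction
    to synonymous codons, curation of coding-sequence corpora (validation,
    per-species deduplication, taxon stratification, train/test splitting),
    species typing by relative synonymous codon usage (RSCU) with k-means
    cluster token-type IDs, a compact disentangled-attention transformer
    encoder with a weight-tied language head trained by masked language
    modeling, synthetic coding-sequence generators with planted codon-level
    structure, frozen-embedding linear probing with repeated cross-validation
    and paired t-tests, synonymous-mutation sensitivity scans, and geometric
    analysis of codon embeddings (PERMANOVA, PCA, t-SNE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
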