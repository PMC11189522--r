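Package: ssnplm
Title: Sequence Similarity Networks and Protein Language Models for Enzyme Family Exploration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the sequence-function space of protein
    families such as the GH29 alpha-L-fucosidases. Builds percent-identity
    sequence similarity networks (SSN) from redundancy-reduced sequence sets,
    analyses their clusters (size ranks, singletons, convergence ratios), and
    trains a lightweight BERT-style protein language model with masked
    language-model pre-training plus an attention classification head that
    assigns new sequences to SSN clusters. Classifier quality is reported as
    accuracy and exponential cross-entropy (ECE) perplexity. A synthetic
    family-structured corpus generator makes the whole pipeline testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
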