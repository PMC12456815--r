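Package: tadwalk
Title: Assessing Random-Walk Smoothing of Hi-C Contact Matrices for TAD Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate Hi-C contact matrices with known topologically
    associating domain (TAD) structure, balance them into doubly stochastic
    transition probability matrices with the Knight-Ruiz algorithm, smooth them
    by finite-step random walks (RWS) or random walk with restart (RWR,
    including the closed-form limiting matrix), call domains with an
    insulation-style boundary detector, and score the congruence between
    detected and true domain partitions with the adjusted Rand index.
    Replicated simulation studies quantify whether random-walk smoothing helps
    or hurts downstream TAD detection across step counts, restart
    probabilities, and data sparsity levels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
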