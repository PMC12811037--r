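Package: noteqc
Title: Quality Assessment, Controlled Corruption and Robustness
    Benchmarking for Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify token-level error rates in free-text clinical
    progress notes, inject controlled misspelling and whitespace-merge errors
    at target rates with ground-truth annotations, detect and correct errors
    through pluggable backends (a dictionary reference implementation and a
    mockable language-model adapter), build TF-IDF and mean-pooled embedding
    document representations, and measure how classifier performance (ROC-AUC)
    degrades as text quality declines. Ships a synthetic clinical-note
    generator with class-informative vocabulary so the whole pipeline is
    testable without access to restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
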