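Package: lexacq
Title: Cross-Linguistic Predictors of Early Word Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models which properties of words predict how early children learn
    them, across languages. Derives word-level predictors (frequency, solo and
    utterance-final frequency, mean length of utterance in words, length in
    phonemes, and adult rating norms) from child-directed-speech corpora, fills
    missing predictor values by iterative regression imputation, fits
    per-language mixed-effects logistic models of vocabulary-checklist
    responses with by-word random intercepts and age slopes, and quantifies the
    cross-language consistency of predictor effects against a shuffled
    bootstrap baseline, with hierarchical clustering of effect profiles.
    Includes a synthetic-data generator with known ground truth for validating
    the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    glmmTMB,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
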