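Package: seqfx
Title: Sequential Effects in Binary Choice Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sequential effects in binary choice data,
    such as human-generated "random" sequences and two-armed operant learning
    sessions. Implements lagged logistic choice models with weighted maximum
    likelihood, reward-augmented value models, five next-symbol predictors
    under within-participant and leave-one-participant-out cross-validation,
    population heterogeneity summaries (mean, quadratic mean, signal-to-noise
    ratio) with bootstrap confidence intervals, model-free deviation-from-
    randomness statistics with Monte-Carlo chance bands, and an exponentially
    discounted stationarity scan. Includes seedable generators for fair-coin,
    heterogeneous lagged-logistic, and operant-learning populations so every
    analysis stage can be exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
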