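Package: hkmlearn
Title: Exhaustive Learning of Human-Computable Boolean Decision Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns short Boolean decision rules that a person can evaluate
    mentally: at most four variables, each used once, combined with at most
    four operators drawn from AND, OR, NOT and a thresholded Boolean SUM
    (an M-of-N count). Raw tabular features are binarized into candidate
    threshold atoms without imputing missing values, and the best (formula,
    feature-subset) pairs are found by exhaustive, deterministic search over
    a precomputed catalog of minimal admissible expressions. Includes a
    multi-instance train/test harness with a stability statistic and its
    empirical curve, precision-recall summaries of the top models by rule
    size, complexity accounting for the search space, and seeded synthetic
    generators (planted rules with label noise and missingness, and a Nim
    game-winner dataset).
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
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
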