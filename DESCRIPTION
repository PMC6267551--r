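Package: nof1bf
Title: Bayes Factors for Informative Hypotheses in Multiple N-of-1
    Binomial Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian evaluation of informative (inequality-constrained)
    hypotheses on condition-wise success probabilities in within-subject
    N-of-1 experiments with dichotomous outcomes.  Hypotheses such as
    "pi1 > pi2 > pi3" are encoded as constraint matrices and evaluated per
    person with encompassing-prior Bayes factors obtained from conjugate
    Beta-binomial Monte Carlo (complexity and fit).  Per-person Bayes
    factors are aggregated over persons into the product Bayes factor
    (P-BF), its geometric mean (gP-BF), the evidence rate (ER) and the
    stability rate (SR), and a simulation-based design analysis helps
    choose the number of persons P and replications R before data
    collection.
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
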