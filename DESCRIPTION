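Package: shrinkstab
Title: Stability of Shrinkage and Penalization in Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how unstable uniform shrinkage factors and
    penalized-regression tuning parameters are when developing clinical
    prediction models, and what that instability does to calibration in new
    individuals. Provides simulation of binary-outcome model-development
    scenarios (20 standard-normal predictors, 5 weakly correlated true
    predictors, 50% event prevalence) and continuous-outcome fixtures at
    chosen apparent R-squared; closed-form (heuristic) and bootstrap
    estimation of the uniform shrinkage factor with percentile confidence
    intervals; ridge, lasso and elastic-net logistic regression with
    cross-validated and bootstrap-cross-validated tuning; external-validation
    metrics (c-index, Nagelkerke R-squared, calibration-in-the-large,
    calibration slope); and a seeded Monte-Carlo scenario runner that
    summarizes the variability of shrinkage and tuning estimates and of
    downstream predictive performance. All results are returned as tidy
    tibbles, with ggplot2 autoplot methods and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glmnet,
    ggplot2,
    generics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
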