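Package: famlift
Title: Simulation and Analysis of Object-Family Motor Memory Lifting Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how motor memories of object weight are
    organized into categories ("families"). Provides the full quantitative
    pipeline for object-lifting experiments in which participants predict the
    weights of visually similar objects: constrained pseudo-random trial
    schedules for laboratory and web-based task variants, a mass-spring-damper
    simulation of the object release phase, generative learner agents
    implementing the competing object-families and associative-map hypotheses,
    trial- and participant-level preprocessing (robust outlier exclusion,
    imputation, non-learner screening), family-level statistics (family-predicted
    weight, outlier-learning tests, single-trial generalization, response-time
    analyses), univariate Gaussian-mixture bimodality analysis with AIC model
    comparison and parametric-bootstrap confidence intervals, and
    simulation-based power analysis for detecting bimodality.
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
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
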