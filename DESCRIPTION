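Package: bmitrends
Title: Hierarchical Bayesian Estimation of Body-Mass Index Trends from
    Heterogeneous Population Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating national, regional and worldwide trends in
    mean body-mass index (BMI) and in growth-reference BMI categories from
    heterogeneous study-level data. Implements LMS (Box-Cox) growth-reference
    z-scores and category classification, a Bayesian hierarchical model with
    linear trends, second-order random-walk smoothing, hierarchical cubic age
    splines and study-quality adjustments fitted by a blocked Gibbs/Metropolis
    sampler, and the post-processing that turns posterior draws into
    age-standardised means, category prevalences, affected counts, credible
    intervals, trend posterior probabilities and count-change decompositions.
    A synthetic-data module generates ground-truth worlds and study databases
    with the statistical structure the model assumes, so every stage is
    testable end to end.
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
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
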