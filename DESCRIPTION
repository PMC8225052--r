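Package: dietaging
Title: Dietary Diversity Scores, Healthy Aging Scores, and Their Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the eight-food-group dietary diversity score (DDS) from
    multi-day 24-hour dietary recalls, builds a composite healthy aging score
    (HAS) from physical functional limitation, comorbidity, cognitive function
    and perceived stress, and fits the covariate-adjusted association models
    linking the two: linear models for the composite, proportional-odds models
    for its components, multinomial models for self-reported life quality,
    median-assignment trend tests, and subgroup analyses with likelihood-ratio
    interaction tests. Ships a seeded synthetic longitudinal cohort generator
    emulating the structure of a two-baseline-wave nutrition survey with
    planted diet-outcome effects, so every stage of the pipeline can be
    validated end to end without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    lmtest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
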