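Package: nutshift
Title: Food-Pattern Substitution Modeling for Dietary Recall Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models partial replacement of meat with walnuts (or other
    food-pattern substitutions) in 24-hour dietary recall microdata at
    escalating doses, and estimates the downstream consequences for the
    population: usual nutrient-intake distributions via a Box-Cox linear
    mixed model with person-level random effects, nutrient adequacy by the
    EAR cut-point and AI methods, Healthy Eating Index 2015 diet quality by
    the population-ratio method, balanced repeated replication (Fay) survey
    variance, and a food-cost model with CPI inflation adjustment. Ships a
    synthetic cohort generator with known ground truth so the full pipeline
    is testable without survey microdata.
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
    lme4,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
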