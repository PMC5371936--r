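Package: cohortdem
Title: Stage-Structured Demography from Daily Insect Cohort Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates Lefkovitch stage-structured projection matrices from
    daily cohort census and oviposition tables, derives demographic parameters
    (population growth rate, net reproductive rate, generation time, stable
    stage distribution, reproductive values, sensitivities and elasticities),
    decomposes treatment differences in growth rate with fixed-design life
    table response experiment (LTRE) analysis, and reproduces the standard
    treatment-comparison statistics used in insect life-table studies.
    Includes an individual-based stochastic cohort simulator with known
    ground truth for validating the estimators, parameterised for the coffee
    berry borer (Hypothenemus hampei).
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
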