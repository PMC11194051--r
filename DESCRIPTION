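Package: metflexr
Title: Metabolic Flexibility Analysis from Indirect Calorimetry, Clamp,
    Exercise and Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for whole-body energy-metabolism studies:
    steady-state detection in breath-by-breath respiratory gas exchange,
    stoichiometric carbohydrate and fat oxidation rates, hyperinsulinemic-
    euglycemic clamp processing (M value, non-oxidative glucose disposal),
    graded maximal cycle-ergometer test processing (VO2max, exercise
    metabolic flexibility, delta efficiency), 6-second accelerometer epoch
    classification and daily activity summaries, a synthetic-cohort
    generator with plantable cross-sectional effect structure, and the
    covariate-adjusted association stage (standardized betas, partial
    correlations, median-split contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
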