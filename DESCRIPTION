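Package: pbdasub
Title: Dairy-to-Plant-Based-Alternative Substitution Modeling for Dietary Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gram-for-gram substitution modeling of dairy foods with plant-based
    dairy alternatives (PBDA) in weighed dietary records of children and
    adolescents. Derives consumption-weighted per-100 g composition and
    environmental-indicator profiles (greenhouse gas emission, land use) for
    dairy and PBDA subgroups, runs substitution scenarios at 25-100%
    replacement levels, scores nutrient adequacy against age- and sex-specific
    dietary reference intakes (%DRI) or percent of energy (%E), and compares
    scenarios to current intake with covariate-adjusted ANOVA and Tukey
    contrasts. Includes a synthetic cohort generator emulating the structure of
    3-day weighed dietary record studies so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
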