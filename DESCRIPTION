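Package: phenoeff
Title: Phenotyping Efficiency Analysis for Early Drought-Tolerance Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the efficiency of early greenhouse-platform
    phenotyping traits as predictors of field drought tolerance in crops such
    as soybean. Computes classical growth-analysis traits (shoot dry weight
    from leaf area, relative expansion rate, net assimilation rate, allometric
    ratios), water-use traits (gravimetric transpiration, transpiration
    efficiency), and two-segment transpiration-rate responses to vapour
    pressure deficit; derives drought susceptibility indices and repeatability
    from variance components; scores every trait-by-time-by-treatment
    combination under a four-criterion selection framework (significance,
    cost-adjusted determination ratio, earliness, repeatability); and analyses
    multi-environment field trial networks with a saturating yield-vs-water
    envelope fit, water-limitation classification, and genotype tolerance
    estimates validated against platform traits. Includes seeded synthetic-data
    generators for platform experiments and trial networks with known ground
    truth.
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
    lme4,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
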