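Package: vitdcea
Title: Cost-Effectiveness Analysis of Vitamin D Supplementation to Prevent Rickets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-tree cost-effectiveness analysis of providing free
    vitamin D supplementation to pregnant women and children under four
    years of age to prevent nutritional rickets, stratified by skin-tone
    subgroup. Implements a two-stage cohort decision tree (4-year base
    case and lifetime scenario), deterministic and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    univariate (tornado) sweeps, threshold analysis by bisection on net
    monetary benefit, incidence estimation from registry case counts and
    census denominators, NHS-tariff style costing with discounting, and a
    seeded synthetic-data generator that emulates the observational
    dataset the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
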