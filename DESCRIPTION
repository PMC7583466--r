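Package: avipref
Title: Street-Tree Availability and Bird Foraging-Preference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the value of urban street trees to foraging
    birds. Computes species importance values (relative density plus relative
    dominance from diameter-at-breast-height inventories), reduces raw bird
    detections to independent feeding-observation units (flock collapsing, a
    100-m pseudo-replication rule, and a first-tree rule), and tests feeding
    use against street-tree availability with chi-square goodness-of-fit tests
    and preference/aversion indices. Community structure across a
    socioeconomic gradient is compared with a permutation ANOSIM on
    square-root Bray-Curtis dissimilarities, ANOVA or Kruskal-Wallis tests
    with multiple-comparison letters, and feeding-bird density is related to
    street-tree predictors through negative-binomial generalized linear models
    ranked by AIC. A synthetic-data generator emulates the income-stratified
    study design so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    vegan,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
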