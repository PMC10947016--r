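Package: fibrescen
Title: Dietary Fibre Reformulation Scenario Modelling for Diet Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the population impact of raising the fibre content of
    white and wholemeal flour. Scales fibre densities of flour-based food
    items in individual-level multi-day diet diaries, recomputes per-person
    daily fibre intake with an exact decomposition of the change by food
    category, and summarises weighted mean intake and the proportion of each
    sex and age group reaching its recommended intake under current and
    reformulated compositions. Includes a quantitative model of white-flour
    fibre composition (arabinoxylan, beta-glucan, fructans, cellulose,
    arabinogalactan peptide) with arabinoxylan substitution and
    water-absorption arithmetic, and a seeded synthetic diary generator
    with closed-form expected scenario effects for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
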