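Package: chemostoich
Title: Stoichiometric Yield Modelling and Chemostat Physiology for
    Engineered Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of aerobic, glucose-limited
    chemostat cultures of product-forming Saccharomyces cerevisiae. Provides
    a curated, element-balanced stoichiometric model of yeast central carbon
    metabolism extended with the de novo resveratrol (phenylpropanoid)
    pathway, solved at zero growth by linear programming to obtain maximum
    theoretical product yields, ATP accounting by source (glycolytic and TCA
    substrate-level phosphorylation, oxidative phosphorylation) and net
    overall conversion reactions under alternative NAD(P)-cofactor
    scenarios. A companion physiology pipeline computes biomass-specific
    rates, yields and carbon recoveries from steady-state chemostat records,
    estimates maintenance coefficients by ordinary least squares on the
    linear rate relation, decomposes substrate uptake over growth,
    maintenance and product formation (Herbert-Pirt), and handles Monod
    residual-substrate kinetics. A synthetic chemostat-data generator with
    configurable noise makes every estimator testable end to end.
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
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
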