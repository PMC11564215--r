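Package: tundraN
Title: Gross Nitrogen Transformations in Organic Tundra Soil from 15N Pool Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microbial nitrogen transformations in
    organic (tundra) soils: fluorometric quantification of free amino acids
    with ammonium correction, protein depolymerisation rates from
    toluene-inhibited slurry time courses, Kirkham-Bartholomew 15N
    pool-dilution estimators of gross nitrogen mineralisation,
    nitrification and inorganic-N consumption, turnover times of
    plant-available nitrogen pools, per-area flux scaling, and the nested
    mixed-effect ANOVA inference layer (Satterthwaite F tests, Tukey and
    interaction-conditioned contrasts, marginal/conditional R-squared).
    Includes a forward simulator of the isotope assays and the full
    blocked field design so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    lme4,
    lmerTest,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
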