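Package: plastflux
Title: Metabolic Plasticity and Food-Web Energy Flux Under Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling size- and temperature-dependence of invertebrate
    metabolic rate with and without metabolic plasticity (a chronic-temperature
    dependence of the allometric exponent and activation energy), processing
    closed-chamber respirometry traces into individual metabolic rates, selecting
    linear mixed-effects rate models by AIC, solving steady-state energy-flux
    balance on food webs, comparing +2 degree Celsius warming scenarios between
    plasticity and no-plasticity models with exact paired Wilcoxon signed-rank
    tests, and diagnosing spatial autocorrelation (Mantel test, Moran's I,
    semivariogram cloud). Includes synthetic-data generators for respirometry
    datasets, oxygen traces and solvable food webs so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
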