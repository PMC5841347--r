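Package: nestarid
Title: Trait-Environment Analysis of Egg Shape and Nest Type on Equal-Area Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Continental-scale comparative analysis of avian egg elongation
    and nest architecture against climate. Builds species assemblages on a
    100 km equal-area (Albers) grid from breeding occurrence records, derives
    vapour-pressure-deficit and canopy (leaf-area-index) surfaces, screens
    cells with a Chao2 sampling-completeness index, and fits the assemblage
    trait-environment models: one-way ANOVA with Tukey pairwise comparisons
    and a family random intercept at the species level; OLS with a VPD x LAI
    interaction, Moran's I correlograms, and maximum-likelihood simultaneous
    autoregressive (SAR) spatial-error models with Nagelkerke pseudo-R2 at
    the assemblage level. A seeded synthetic-world generator provides
    species, surfaces, occurrences and SAR responses with known parameters
    for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), ape, lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
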