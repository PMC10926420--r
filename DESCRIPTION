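Package: nutriscape
Title: Nutritional Geometry of Lifespan and Reproduction on Protein-Carbohydrate Diet Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nutritional-geometry experiments in which animals feed on
    liquid diets varying in protein to carbohydrate (P:C) ratio and total
    concentration. Converts tube-length measurements into evaporation-corrected
    protein and carbohydrate intakes, estimates linear, quadratic and
    correlational nutrient effects on life-history traits with replicate as a
    random factor, compares nutritional landscapes between groups by sequential
    model building with partial F-tests, fits thin-plate-spline nutritional
    landscapes and locates trait optima with bootstrap optimum regions, and
    analyses dietary self-selection (random-feeding nulls, regulated intake
    points, regulation comparisons). Includes synthetic-data generators that
    emulate a no-choice diet-grid experiment and a paired-diet choice experiment
    on selection lines of the marula fly (Ceratitis cosyra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
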