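Package: infraccess
Title: Population-Weighted Infrastructure Access, Inequality and Health
    Associations on Gridded Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map economic, social and environmental infrastructure
    on a regular latitude-longitude grid, calibrate socio-economic layers
    against night-time lights, compute population-weighted access per
    administrative unit, quantify within-unit access inequality with a
    population-weighted Gini coefficient, classify units into high/medium/low
    composite categories, and relate access and inequality to health outcomes
    (HALE, DALYs) with linear mixed-effects models, robust standard errors
    and random-forest variable importance. Includes a synthetic-world
    generator with known ground truth so the full pipeline is testable
    without any external geospatial download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    car,
    randomForest,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
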