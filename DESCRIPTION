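Package: sdmspill
Title: Spatial Durbin Panel Models and Spillover Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial econometric analysis of balanced region-by-year panels:
    construction of contiguity, inverse-distance and economic-distance
    spatial weight matrices; global Moran's I screening with randomization
    and permutation inference; maximum-likelihood spatial Durbin models with
    individual fixed or random effects and Hausman model selection;
    decomposition of coefficients into direct, indirect and total effects by
    the LeSage-Pace partial-derivatives method with Monte-Carlo inference;
    and a synthetic data generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
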