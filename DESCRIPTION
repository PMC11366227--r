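Package: permeaphen
Title: Water-Soaking Phenotyping and Skin Water Permeance for Strawberry
    Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immersion-assay phenotyping of water
    soaking in strawberry. Converts raw per-fruit gravimetric and
    refractometric measurements into skin water permeance and related
    biophysical traits, fits lag-parameterised Gompertz curves to
    water-soaking time courses to extract time lag and maximum rate,
    computes cuticle and achene morphometrics, summarises traits per
    genotype, and reproduces the study-level statistical layer (Pearson
    correlation tables with significance stars, water-soaking versus
    log-permeance regression, Tukey and pairwise Mann-Whitney letter
    displays, Dunnett comparisons against a control). Includes a seeded
    synthetic multi-collection panel generator with known latent truth so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    minpack.lm,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
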