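Package: soilniche
Title: Causal Networks, Niche Models and Climate Projections for Soil Bacterial Relative Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models soil bacterial relative abundances from climate, vegetation
    and soil drivers with recursive observed-variable structural equation
    models (path analysis), characterises niche space along environmental
    gradients with the Huisman-Olff-Fresco family of response curves, measures
    global (Abouheif's Cmean) and local (local Moran's I / LIPA) phylogenetic
    signal of model-derived trait indicators, clusters taxa into environmental
    response groups with ternary soil/vegetation/climate coordinates, and
    projects relative abundances and community displacement under future
    driver scenarios. Includes a synthetic-data generator with known causal,
    unimodal and phylogenetic ground truth, plus rarefaction, gene-copy-number
    correction and taxonomic rank aggregation for abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
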