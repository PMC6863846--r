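Package: karstflora
Title: Macroecological Analysis of Karst Floras from Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for evaluating the species richness,
    endemism and conservation importance of karst landscapes from herbarium
    occurrence records. Provides coordinate and taxonomic cleaning with
    backbone-congruence accounting, equal-area gridding at 50 km and 10 km,
    per-cell richness with bootstrap species-area null models and quantile
    outlier classification, weighted and corrected weighted endemism with
    randomization significance, range-size and small-range-species statistics,
    resampling comparisons of karst against its surrounding study area,
    keyword-based validation of karst maps against collection-label metadata,
    and IUCN category cross-tabulation. A synthetic-data module generates
    occurrence tables, karst polygons, taxonomic backbones and red-list tables
    with the statistical structure the analysis assumes, so the whole pipeline
    is testable end to end without any external download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    vegan,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
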