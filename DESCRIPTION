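Package: soilprotist
Title: Soil Protistan Community Ecology: Diversity, Null-Model Assembly and
    Crop-Quality Links
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of soil protistan (18S amplicon) ASV tables
    across crop cultivation modes and growth stages: table preparation (taxon
    exclusion, singleton removal, seeded rarefaction), alpha and Bray-Curtis
    beta diversity with PCoA, PERMANOVA and Tukey group comparisons,
    phylogenetic null-model community assembly (betaMNTD, betaNTI via
    tip-shuffle nulls, abundance-based Raup-Crick) with partitioning into five
    ecological processes, trophic functional-group composition, a composite
    z-score production index for fruit quality with regressions on community
    diversity and composition, environmental-driver analysis (redundancy
    analysis and random-forest importance), and a synthetic-data generator
    that emulates a cultivation-mode by growth-stage field design with
    phylogenetically conserved niches along a nitrogen-like gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    picante,
    randomForest,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
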