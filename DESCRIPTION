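Package: treeAtlas
Title: Tree Species Distribution, Composition and Climate-Response Modelling
    on Synthetic Worlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for macroecological analysis of tree
    species: species distribution modelling with an ensemble of random
    forests and gradient-boosted trees, geographic range constraints built
    from native-country polygons and occurrence support, max-TSS threshold
    binarisation by cross-validation, taxonomic (Sorensen NMDS) and
    phylogenetic (branch-weighted Hellinger PCA) ordination of community
    matrices, forest-cover-restricted occupancy range sizes, and
    ecoregion-level climate-change response metrics with biome-level
    synthesis.  A self-contained synthetic world generator (environmental
    raster stack, country and ecoregion tessellations, Gaussian species
    niches, occurrences, survey plots, tree cover, future climate, Yule
    phylogeny) provides ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    geosphere,
    mgcv,
    ape,
    phangorn,
    vegan,
    ranger,
    xgboost,
    cluster,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
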