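Package: fourwayQTL
Title: QTL Mapping and Density-Response Analysis in Four-Way RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for four-way recombinant inbred
    line (FW-RIL) populations evaluated under contrasting planting densities.
    Provides a founder-origin-tracking FW-RIL simulator with split-block
    phenotypes, descriptive trait summaries, split-block analysis of variance
    with expected-mean-square variance components and broad-sense heritability,
    the conditional-variable response-to-density statistic, a four-founder
    interval-mapping genome scan (plain and cofactor-adjusted) with LOD-based
    QTL calling and naming, a moment-based decomposition of QTL effects into
    additive and additive-by-density components, a single-marker association
    scan with an LD-decay utility, and cross-result reporting (stability
    classification, candidate selection, linkage-association co-location,
    Venn tallies, and candidate-gene windows).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
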