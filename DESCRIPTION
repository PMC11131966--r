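Package: frnet
Title: Gene- and Protein-Level Functional Redundancy of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies microbial protein families as specialist, niche, or
    essential functions by contrasting gene-level and protein-level functional
    redundancy computed from paired taxon-by-function incidence networks (gene
    content network, GCN; protein content network, PCN) weighted by a taxonomic
    relative-abundance profile. Includes per-function redundancy, network
    degree, connectance and NODF nestedness; a consumer-resource community
    assembly simulator that plants the three function types in synthetic
    genomes and exports ground-truth-labelled networks; Gaussian-mixture,
    k-means and quadratic-discriminant classifiers over the redundancy or
    degree feature planes; abundance-percentile detection-depth sensitivity
    sweeps; and metaproteomic intensity normalization with fold-change and
    rank-based group-comparison statistics.
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
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    withr,
    deSolve
Config/testthat/edition: 3
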