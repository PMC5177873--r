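Package: ceRank
Title: Convergent-Evidence Gene Prioritization by Weighted Vote Counting
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes candidate genes and biomarkers by integrating
    heterogeneous molecular studies as binary evidence layers. Each layer
    receives a custom weight built from three self-importance factors
    (phenotype precision, homology conversion, sample size) with a penalty
    for linkage layers paired with association layers; molecules are ranked
    by the weighted arithmetic mean of their detection indicators, a top
    quantile is selected overall and within subphenotype classes, and the
    top set is characterized by Fisher-exact over-representation and a
    triangle-seeded interaction-network builder. Includes region-to-gene
    mapping for association and linkage evidence, cross-species homolog
    translation, a planted-signal synthetic benchmark, and a config-driven
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneSetEnrichment, NetworkEnrichment, GenePrediction
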