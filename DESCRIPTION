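Package: tnscreen
Title: Transposon-Insertion Selection Screens for Phage Resistance
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transposon insertion sequencing (Tn-Seq) selection
    screens, from per-site insertion read counts to called resistance loci.
    Implements paired total-read normalization, per-gene log2 fold changes,
    exact and tie-corrected Mann-Whitney U testing, two-replicate hit calling
    with a unique-insertion filter and a small-gene review flag, replicate
    reproducibility statistics, correlation-threshold clustering of gene
    phenotypic profiles, and phage adsorption / efficiency-of-center-of-
    infection (ECOI) kinetics statistics. Ships a synthetic generator for
    transposon libraries under phage selection (essential-gene voids, fitness
    cost depletion, survival enrichment, plating bottlenecks, overdispersed
    sequencing noise) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Biostrings,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
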