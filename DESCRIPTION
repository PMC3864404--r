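Package: clonescape
Title: Multi-Region Clonal Evolution Analysis for High-Grade Serous Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal architecture of multi-region tumour
    sequencing studies of high-grade serous ovarian carcinoma. From deep
    amplicon read counts it calls per-sample mutation presence/absence with an
    exact binomial test, computes mutation-conservation statistics, and builds
    Pearson-distance neighbour-joining phylogenies rooted at an aberration-free
    control. From allele-specific copy-number segments it classifies zygosity
    states (NLOH, ALOH, deletions), scores compound-event burden, builds
    Euclidean-distance architecture trees, and detects whole-genome-doubling
    signatures between samples. Plasma circulating tumour DNA counts are tested
    for mutation detection with exact binomial tests under
    Benjamini-Hochberg false-discovery control, including the minimum
    detectable allelic ratio and ancestral-clone enrichment. Cellular
    frequencies are estimated with a purity- and copy-number-adjusted
    estimator, and intra-sample clonal diversity is scored as their
    interquartile range. A clonal-evolution simulator generates ground-truth
    clone trees, regional clone mixtures, amplicon depths, copy-number
    profiles and plasma counts for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
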