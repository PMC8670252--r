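Package: saltomics
Title: Integrative Multi-Omics Analysis of Cyanobacterial Salt Acclimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating time-resolved
    transcriptome, proteome, and metabolome measurements of salt-stressed
    cyanobacteria. Provides soft (fuzzy c-means) clustering of temporal
    expression profiles with closed-form fuzzifier estimation and elbow
    selection of the cluster count, strand-aware antisense-RNA/mRNA pair
    detection and correlation-based classification, Hi3-style absolute
    protein quantification with fraction-weighted fold-change combination,
    transcriptome-proteome correlation and multi-dataset consensus
    filtering, hypergeometric KO-term enrichment, and internal-standard
    metabolite normalization. A synthetic-data generator with known ground
    truth emulates the structure of the real datasets so every stage has a
    recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
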