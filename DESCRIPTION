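Package: proteomining
Title: Proteomining Clustering: Active Biosynthetic Gene Cluster Discovery
    from Label-Free Quantitative Proteomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies active biosynthetic gene clusters (BGCs) in bacterial
    genomes from replicate label-free shotgun-proteomics spectral counts taken
    in two fermentation states (secondary-metabolite producing versus
    non-producing growth phase). Spectral counts are converted to normalized
    spectral abundance factors (NSAF) with a detection filter and floor
    imputation; per-protein fold changes and p-values are turned into signed
    two-tier node scores; scored nodes are clustered by open-reading-frame
    (ORF) proximity along the genome, span-normalized cluster scores are
    computed, chimeric clusters are decoupled by an exact contiguous-partition
    search, and the surviving proteomining-based clusters (PBCs) are reported
    with optional BED/GFF3 interval exports. A seeded synthetic-data generator
    with planted clusters, and monoisotopic adduct m/z utilities for
    confirming candidate metabolites by LC-MS, are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
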