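Package: methbins
Title: DNA Methylation Sub-Patterns Across Gene Regions and Promoter Bins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses whole-genome bisulfite sequencing (WGBS) CpG methylation
    calls across the neighbourhood of annotated genes. Each gene's +/- 20 kb
    neighbourhood is partitioned into twelve strand-aware regions (up20 to
    down20 flanks plus 5'UTR, exon, intron and 3'UTR) and the promoter
    (TSS +/- 2 kb) into twenty 200 bp bins. The package aggregates per-CpG
    methylation into region- and bin-level matrices with replicate- and
    stage-level averaging, classifies promoter bins by CpG density (HCG, ICG,
    LCG), discretises genes into hypo/moderate/hyper methylation states and
    counts state transitions between developmental stages, correlates
    methylation with log2 RPKM expression per region and bin (with PCA over
    bin correlation profiles), and selects differentially methylated genes at
    the first promoter bin with fold-change, t-test, cohort-mean and
    expression-direction filters. A fully seeded synthetic-data generator
    produces genome, annotation, stage-structured methylomes and matched
    expression with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
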