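Package: epimung
Title: Whole-Genome Bisulfite Methylome Analysis for Two-Cultivar Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis of plant genomes, modelled on a two-cultivar mungbean (Vigna
    radiata) comparison. Provides binomial methylation calling calibrated
    against an unmethylated chloroplast control, CG/CHG/CHH context
    enumeration, weighted methylation levels, metagene and genomic-window
    profiles, sliding-window differentially methylated region (DMR) detection
    by Fisher's exact test, classification of SNP-induced cytosine context
    transitions (obligate epialleles), methylation-expression integration,
    and a fully seeded synthetic-data generator with ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
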