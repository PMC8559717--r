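Package: germload
Title: Mutational Load at Germline Regulatory Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the enrichment of rare sequence variants at active
    regulatory sites in the germline. Classifies singleton and common short
    variants from VCF allele counts, extracts structural-variant breakpoints
    under a reciprocal-overlap grouping rule, builds motif families from
    position weight matrices and scans genomes for binding sites, and tests
    variant-site association with circular-permutation null models, shifted
    local Z-score profiles, fold-enrichment statistics, enhancer odds ratios
    and homotypic motif-clustering ratios. Ships a synthetic-data generator
    that plants known effect sizes so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
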