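Package: rnasnpeval
Title: Evaluation of SNP Calling Strategies for RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("rnasnpeval", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark single-nucleotide variant detection from
    bulk RNA-seq alignments against a truth genotype set. Implements both
    pre-alignment (exact sequence) and post-alignment (mapped coordinate)
    duplicate-read handling, a minimal threshold pileup genotype caller,
    SNP-cluster and accessibility-mask filters, coverage- and
    zygosity-stratified specificity and sensitivity, overlap between call
    sets, and rescue of putative false positives using orthogonal DNA
    evidence alignments. A synthetic-data module simulates an annotated
    reference, planted diploid variants, expression-weighted reads with
    PCR duplicates and sequencing errors, and writes all standard-format
    fixture files (FASTA, SAM, VCF, BED, refFlat), so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
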