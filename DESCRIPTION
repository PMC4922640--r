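Package: ramscan
Title: Tiered Sliding-Window Detection of Regions of Altered Methylation
    from Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide detection of regions of altered methylation (RAMs)
    from methylation-enrichment sequencing read counts. The genome is tiled
    into overlapping 100 bp windows (50 bp step), per-window read counts are
    tested between exposure groups with a negative-binomial exact test using
    empirical-Bayes moderated (tagwise) dispersion, and candidate windows are
    post-filtered for within-group consistency and flanking-window support.
    An empirical false-discovery rate is estimated from male-versus-female
    contrasts under the assumption that autosomal sex hits are false
    positives. Windows are placed in genomic context (CpG island, shore,
    shelf; promoter, exon, intron, intergenic, repeat; nearest TSS), and
    methylation calls are integrated with RNA-seq differential expression by
    inverse effect direction. A synthetic-data module simulates miniature
    genomes, annotation tracks, enrichment read positions and expression
    counts with known ground truth for end-to-end validation.
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
    GenomeInfoDb,
    SummarizedExperiment,
    edgeR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
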