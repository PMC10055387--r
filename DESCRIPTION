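Package: pairmark
Title: Cluster-Specific Marker Gene Pair Selection and Knock-In Homology Arm Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects pairs of genes that uniquely co-mark a single cluster of a
    clustered single-cell RNA-seq atlas against a whole-body background.
    Candidate genes are filtered by the intersection of an organ-level Tau
    specificity index, a within-cluster dispersion (variance/mean) cap, and a
    one-vs-rest Welch t-test; all candidate pairs are then scored by a weighted
    combination of the metagene (pair-average) Wilcoxon rank-sum AUROC, the
    number of off-target clusters co-marked by both genes, and the pair's
    minimum Tau. Includes a negative-binomial synthetic atlas generator with
    planted ground-truth marker pairs for end-to-end validation and
    hyperparameter calibration, and a designer of in-frame CRISPR knock-in
    homology arms (left arm ending on a codon's first nucleotide, never a
    thymine) from a genome FASTA and GFF3 annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlas-io.R'
    'donor-design.R'
    'gene-metrics.R'
    'pair-scoring.R'
    'pairmark-package.R'
    'run-commands.R'
    'synthetic-atlas.R'
    'utils.R'
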