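# Fixture builders shared across test files. Everything is generated in code;
# no data files are read from disk except those a test writes itself.

# A fully annotated (and optionally normalized) toy atlas from an explicit
# gene x cell count matrix.
makeToyAtlas <- function(counts, clusters, clusterTissues = NULL,
                         normalize = TRUE, scaleTarget = 1e4) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(as.matrix(counts), "CsparseMatrix")))
    if (is.null(clusterTissues)) {
        cl <- sort(unique(clusters))
        clusterTissues <- data.frame(cluster = cl,
                                     tissue = paste0("t_", cl))
    }
    sce <- addClusterAnnotation(
        sce,
        data.frame(cell = colnames(counts), cluster = clusters),
        clusterTissues)
    if (normalize) sce <- suppressWarnings(normalizeAtlas(sce, scaleTarget))
    sce
}

# Exhaustive-enumeration two-sided Wilcoxon p-value: the null distribution of
# the target-group U over all C(n, n1) group assignments of the observed
# values. Independent of the implementation under test.
enumWilcoxonP <- function(values, inTarget) {
    n1 <- sum(inTarget)
    n <- length(values)
    r <- rank(values)
    uObs <- sum(r[inTarget]) - n1 * (n1 + 1) / 2
    assignments <- utils::combn(n, n1)
    us <- apply(assignments, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# Brute-force AUROC: proportion of (target, rest) pairs won by the target
# value, ties counted one half.
bruteAuroc <- function(values, inTarget) {
    xt <- values[inTarget]; xr <- values[!inTarget]
    s <- 0
    for (a in xt) for (b in xr) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(xt) * length(xr))
}

# Brute-force off-target count: explicit double loop over clusters.
bruteKOff <- function(geneA, geneB, markers, target) {
    k <- 0L
    for (cc in colnames(markers)) {
        if (cc == target) next
        if (markers[geneA, cc] && markers[geneB, cc]) k <- k + 1L
    }
    k
}

# A random DNA contig with a planted CDS whose sequence is given; returns the
# contig and the GRanges of the CDS chunks.
plantCds <- function(cdsSeq, contigLen = 2000L, cdsStart0 = 1000L,
                     strand = "+", contig = "chr1", seed = 1L) {
    set.seed(seed)
    bases <- sample(c("A", "C", "G"), contigLen, replace = TRUE)  # T-free bg
    s <- if (strand == "+") cdsSeq else
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cdsSeq)))
    substr0 <- strsplit(s, "")[[1]]
    bases[(cdsStart0 + 1):(cdsStart0 + length(substr0))] <- substr0
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- contig
    gr <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(start = cdsStart0 + 1L,
                         end = cdsStart0 + nchar(cdsSeq)),
        strand = strand)
    list(genome = genome, cds = gr)
}
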