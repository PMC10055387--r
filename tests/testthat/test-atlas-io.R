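# Readers, writers, normalization, pseudobulk.

writeMtxFixture <- function(dir, m, genes, cells, transpose = FALSE) {
    paths <- file.path(dir, c("m.mtx", "genes.tsv", "cells.tsv"))
    Matrix::writeMM(as(if (transpose) t(m) else m, "CsparseMatrix"), paths[1])
    writeLines(genes, paths[2])
    writeLines(cells, paths[3])
    paths
}

test_that("MTX round trip preserves values, zeros, and identifiers", {
    dir <- withr::local_tempdir()
    m <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
    m[1, 1] <- 5; m[3, 2] <- 2
    p <- writeMtxFixture(dir, m, rownames(m), colnames(m))
    sce <- readCountMatrix(p[1], p[2], p[3])
    expect_identical(dim(sce), c(3L, 2L))
    expect_equal(as.matrix(SingleCellExperiment::counts(sce)), m)

    # orientation is resolved from identifier lengths for transposed files
    p2 <- writeMtxFixture(dir, m, rownames(m), colnames(m), transpose = TRUE)
    sce2 <- readCountMatrix(p2[1], p2[2], p2[3])
    expect_equal(as.matrix(SingleCellExperiment::counts(sce2)), m)

    # full write -> read round trip through the package writer
    p3 <- file.path(dir, c("rt.mtx", "rt_g.tsv", "rt_c.tsv"))
    writeCountMatrix(sce, p3[1], p3[2], p3[3])
    sce3 <- readCountMatrix(p3[1], p3[2], p3[3])
    expect_equal(as.matrix(SingleCellExperiment::counts(sce3)), m)
})

test_that("degenerate and invalid matrix inputs are handled", {
    dir <- withr::local_tempdir()
    # empty matrix: declared 3 x 2 with zero nonzeros
    empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(3, 2))
    p <- writeMtxFixture(dir, empty, paste0("g", 1:3), paste0("c", 1:2))
    sce <- readCountMatrix(p[1], p[2], p[3])
    expect_true(all(as.matrix(SingleCellExperiment::counts(sce)) == 0))
    expect_identical(dim(sce), c(3L, 2L))

    # duplicated gene identifier
    writeLines(c("g1", "g1", "g3"), p[2])
    expect_error(readCountMatrix(p[1], p[2], p[3]), "duplicate gene id")

    # square matrix with equal id counts is ambiguous
    sq <- Matrix::sparseMatrix(i = 1, j = 2, x = 3, dims = c(2, 2))
    ps <- writeMtxFixture(dir, sq, paste0("g", 1:2), paste0("c", 1:2))
    expect_error(readCountMatrix(ps[1], ps[2], ps[3]), "ambiguous")

    # negative and non-integer entries
    bad <- Matrix::sparseMatrix(i = 1, j = 1, x = -1, dims = c(3, 2))
    pb <- writeMtxFixture(dir, bad, paste0("g", 1:3), paste0("c", 1:2))
    expect_error(readCountMatrix(pb[1], pb[2], pb[3]), "negative")
    frac <- Matrix::sparseMatrix(i = 1, j = 1, x = 1.5, dims = c(3, 2))
    pf <- writeMtxFixture(dir, frac, paste0("g", 1:3), paste0("c", 1:2))
    expect_error(readCountMatrix(pf[1], pf[2], pf[3]), "non-integer")
})

test_that("dense TSV dialect reads genes x cells with identifier cross-check", {
    dir <- withr::local_tempdir()
    m <- matrix(c(1, 0, 2, 3, 0, 4), 3, 2,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
    dense <- file.path(dir, "dense.tsv")
    write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                dense, sep = "\t", quote = FALSE, row.names = FALSE)
    sce <- readCountMatrix(dense)
    expect_equal(as.matrix(SingleCellExperiment::counts(sce)), m)
    gfile <- file.path(dir, "g.tsv")
    writeLines(c("g1", "gX", "g3"), gfile)
    expect_error(readCountMatrix(dense, genesPath = gfile), "disagrees")
})

test_that("normalization matches the stated transform and preserves zeros", {
    counts <- matrix(c(1, 1, 0, 0), 2, 2,
                     dimnames = list(c("g1", "g2"), c("c1", "c2")))
    sce <- makeToyAtlas(counts, clusters = c("k1", "k1"), normalize = FALSE)
    # cell counts [1, 1], scale 2, pseudocount 1 -> log(1 + 1) each
    expect_warning(sceN <- normalizeAtlas(sce, scaleTarget = 2),
                   "all-zero")
    ln <- as.matrix(SingleCellExperiment::logcounts(sceN))
    expect_equal(unname(ln[, 1]), c(log(2), log(2)))
    expect_true(all(ln[, 2] == 0))  # all-zero cell left all-zero, flagged
    expect_identical(S4Vectors::metadata(sceN)$normalization$emptyCells, "c2")

    # zero pattern identical to source, scale-equivariance in counts
    set.seed(11)
    cm <- matrix(rpois(600, 0.8), 30, 20)
    sce2 <- makeToyAtlas(cm, clusters = rep(c("a", "b"), each = 10),
                         normalize = FALSE)
    sce2 <- suppressWarnings(normalizeAtlas(sce2))
    ln2 <- as.matrix(SingleCellExperiment::logcounts(sce2))
    expect_identical(ln2 == 0, as.matrix(SingleCellExperiment::counts(sce2)) == 0)
    cm3 <- cm; cm3[, 1] <- cm3[, 1] * 7  # rescaling one cell's counts
    sce3 <- suppressWarnings(normalizeAtlas(
        makeToyAtlas(cm3, rep(c("a", "b"), each = 10), normalize = FALSE)))
    expect_equal(as.matrix(SingleCellExperiment::logcounts(sce3))[, 1],
                 ln2[, 1])
})

test_that("pseudobulk is the per-organ mean of normalized values", {
    # one organ, two cells with values [0, 2] for a gene -> mean 1.0
    # (engineered so the normalized value of the expressing cell is exactly 2)
    counts <- matrix(c(0, 1, 10, 1), 2, 2,
                     dimnames = list(c("g1", "g2"), c("c1", "c2")))
    sce <- makeToyAtlas(counts, clusters = c("k1", "k1"), normalize = FALSE)
    sce <- normalizeAtlas(sce, scaleTarget = 11 * (exp(2) - 1) / 10)
    pb <- pseudobulkProfiles(sce)
    expect_equal(unname(pb["g1", 1]), 1.0)

    # gene expressed only in organ A -> organ B entry is 0
    counts2 <- matrix(c(4, 1, 0, 3), 2, 2,
                      dimnames = list(c("gA", "gB"), c("c1", "c2")))
    sce2 <- makeToyAtlas(counts2, clusters = c("k1", "k2"),
                         clusterTissues = data.frame(cluster = c("k1", "k2"),
                                                     tissue = c("A", "B")))
    pb2 <- pseudobulkProfiles(sce2)
    expect_identical(unname(pb2["gA", "B"]), 0)

    # 4 cells, 2 organs: independent per-organ summation oracle
    set.seed(5)
    cm <- matrix(rpois(20, 3), 5, 4)
    sce3 <- makeToyAtlas(cm, clusters = c("k1", "k1", "k2", "k2"),
                         clusterTissues = data.frame(cluster = c("k1", "k2"),
                                                     tissue = c("A", "B")))
    pb3 <- pseudobulkProfiles(sce3)
    ln <- as.matrix(SingleCellExperiment::logcounts(sce3))
    for (g in seq_len(5)) {
        expect_equal(pb3[g, "A"], (ln[g, 1] + ln[g, 2]) / 2)
        expect_equal(pb3[g, "B"], (ln[g, 3] + ln[g, 4]) / 2)
    }

    # one cell per organ: pseudobulk equals that cell's normalized column
    sce4 <- makeToyAtlas(cm[, 1:2], clusters = c("k1", "k2"),
                         clusterTissues = data.frame(cluster = c("k1", "k2"),
                                                     tissue = c("A", "B")))
    pb4 <- pseudobulkProfiles(sce4)
    expect_equal(unname(pb4[, "A"]),
                 unname(as.matrix(SingleCellExperiment::logcounts(sce4))[, 1]))

    # an organ in the map with zero cells is an error
    sce5 <- makeToyAtlas(cm, clusters = rep("k1", 4),
                         clusterTissues = data.frame(
                             cluster = c("k1", "k9"),
                             tissue = c("A", "GHOST")))
    expect_error(pseudobulkProfiles(sce5), "zero cells")
})

test_that("bulk table IO round-trips and validates", {
    dir <- withr::local_tempdir()
    bulk <- matrix(c(0.5, 2, 0, 7, 1.25, 3), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("gut", "ovary")))
    p <- file.path(dir, "bulk.tsv")
    writeBulkTable(bulk, p)
    expect_equal(readBulkTable(p), bulk)
    # write -> read -> write -> read is identity too
    p2 <- file.path(dir, "bulk2.tsv")
    writeBulkTable(readBulkTable(p), p2)
    expect_equal(readBulkTable(p2), bulk)
    bulk[2, 1] <- -1
    writeBulkTable(bulk, p)
    expect_error(readBulkTable(p), "negative")
})

test_that("cluster annotation enforces one cluster per cell and one tissue per cluster", {
    cm <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(cm, "CsparseMatrix")))
    expect_error(addClusterAnnotation(sce,
        data.frame(cell = c("c1", "c1", "c2"), cluster = c("a", "b", "a")),
        data.frame(cluster = "a", tissue = "t")),
        "more than one cluster")
    expect_error(addClusterAnnotation(sce,
        data.frame(cell = c("c1", "c2"), cluster = c("a", "b")),
        data.frame(cluster = "a", tissue = "t")),
        "no tissue annotation")
})

test_that("reports carry one row per scored pair and JSON reparses to the scores", {
    dir <- withr::local_tempdir()
    sim <- simulateAtlas(nClusters = 4, nTissues = 2, cellsPerCluster = 12,
                         nGenes = 60, nDecoyPairs = 1, seed = 2)
    sce <- normalizeAtlas(sim$sce)
    rk <- rankPairs(sce, sim$bulk, target = targetCluster(sim$truth))
    paths <- writeReport(rk, file.path(dir, "report"), format = "both")
    tsv <- read.delim(paths[1], comment.char = "#")
    expect_identical(nrow(tsv), nrow(pairTable(rk)))
    js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
    expect_equal(js$pairs$score, pairTable(rk)$score)
    expect_equal(js$pairs$geneA, pairTable(rk)$geneA)
    expect_equal(js$pairs$kOff, pairTable(rk)$kOff)
    expect_identical(js$metadata$targetCluster, targetCluster(rk))
})
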