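#' @importFrom Matrix readMM writeMM colSums rowMeans t Diagonal sparseMatrix
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts counts
#' @importFrom SummarizedExperiment assay assay<- colData colData<- assayNames
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom utils read.delim write.table head
NULL

.readIdColumn <- function(path, what) {
    ids <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    ids <- as.character(ids)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1L]))
    ids
}

#' Read a gene x cell count matrix
#'
#' Reads a sparse Matrix Market file (`.mtx`) together with one-column gene
#' and cell identifier files, or a dense TSV (genes in rows, header row of
#' cell ids, first column gene ids). The on-disk orientation of an MTX file
#' may be genes x cells or cells x genes; it is resolved by matching the
#' identifier-file lengths, and a square matrix with equally many genes and
#' cells is rejected as ambiguous.
#'
#' @param matrixPath path to the `.mtx` (or dense `.tsv`) count file.
#' @param genesPath,cellsPath one-column TSVs of gene and cell identifiers.
#'   Optional for the dense dialect, where they default to the row/column
#'   names of the TSV and are cross-checked when supplied.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (sparse, genes x cells).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulateAtlas(nClusters = 2, nTissues = 1, cellsPerCluster = 5,
#'                      nGenes = 20, nDecoyPairs = 0, seed = 1)
#' writeCountMatrix(sim$sce, file.path(dir, "m.mtx"),
#'                  file.path(dir, "genes.tsv"), file.path(dir, "cells.tsv"))
#' sce <- readCountMatrix(file.path(dir, "m.mtx"),
#'                        file.path(dir, "genes.tsv"),
#'                        file.path(dir, "cells.tsv"))
#' dim(sce)
#' @export
readCountMatrix <- function(matrixPath, genesPath = NULL, cellsPath = NULL) {
    if (grepl("\\.mtx$", matrixPath, ignore.case = TRUE)) {
        if (is.null(genesPath) || is.null(cellsPath))
            stop("MTX input requires gene and cell identifier files")
        genes <- .readIdColumn(genesPath, "gene")
        cells <- .readIdColumn(cellsPath, "cell")
        m <- readMM(matrixPath)
        if (is(m, "nMatrix")) m <- m * 1  # pattern file: all stored entries 1
        m <- as(m, "CsparseMatrix")
        if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
            if (nrow(m) == ncol(m) && length(genes) == length(cells))
                stop("ambiguous orientation: square matrix with equally many ",
                     "gene and cell identifiers")
        } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
            m <- Matrix::t(m)
        } else {
            stop(sprintf(
                "dimension mismatch: matrix is %d x %d but %d genes and %d cells were supplied",
                nrow(m), ncol(m), length(genes), length(cells)))
        }
    } else {
        tab <- read.delim(matrixPath, header = TRUE, row.names = 1L,
                          check.names = FALSE)
        m <- as(as.matrix(tab), "CsparseMatrix")
        genes <- rownames(tab)
        cells <- colnames(tab)
        if (anyDuplicated(genes)) stop("duplicate gene id in dense table")
        if (anyDuplicated(cells)) stop("duplicate cell id in dense table")
        if (!is.null(genesPath)) {
            g2 <- .readIdColumn(genesPath, "gene")
            if (!identical(g2, genes))
                stop("gene identifier file disagrees with dense table rows")
        }
        if (!is.null(cellsPath)) {
            c2 <- .readIdColumn(cellsPath, "cell")
            if (!identical(c2, cells))
                stop("cell identifier file disagrees with dense table columns")
        }
    }
    if (length(m@x) && any(m@x < 0))
        stop("negative entries in count matrix")
    if (length(m@x) && any(m@x != round(m@x)))
        stop("non-integer entries in count matrix")
    dimnames(m) <- list(genes, cells)
    SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix as Matrix Market plus identifier files
#'
#' Inverse of [readCountMatrix()]; values are written genes x cells.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param matrixPath,genesPath,cellsPath output paths.
#' @return invisibly, the three paths.
#' @export
writeCountMatrix <- function(sce, matrixPath, genesPath, cellsPath) {
    m <- as(counts(sce), "CsparseMatrix")
    writeMM(m, matrixPath)
    writeLines(rownames(sce), genesPath)
    writeLines(colnames(sce), cellsPath)
    invisible(c(matrixPath, genesPath, cellsPath))
}

#' Attach cluster and tissue annotation to an atlas
#'
#' Adds `cluster` and `tissue` columns to the column data and stores the
#' cluster-to-tissue map in the object metadata. Every cell must be annotated
#' with exactly one cluster and every cluster with exactly one tissue.
#'
#' @param sce a SingleCellExperiment.
#' @param cellClusters a two-column data frame (cell_id, cluster_id) or the
#'   path of a headerless TSV with those columns.
#' @param clusterTissues a two-column data frame (cluster_id, tissue_id) or
#'   TSV path.
#' @return the annotated SingleCellExperiment.
#' @export
addClusterAnnotation <- function(sce, cellClusters, clusterTissues) {
    if (is.character(cellClusters))
        cellClusters <- read.delim(cellClusters, header = FALSE,
                                   stringsAsFactors = FALSE)[, 1:2]
    if (is.character(clusterTissues))
        clusterTissues <- read.delim(clusterTissues, header = FALSE,
                                     stringsAsFactors = FALSE)[, 1:2]
    cellClusters[] <- lapply(cellClusters, as.character)
    clusterTissues[] <- lapply(clusterTissues, as.character)
    if (anyDuplicated(cellClusters[[1L]]))
        stop("a cell is annotated with more than one cluster")
    if (anyDuplicated(clusterTissues[[1L]]))
        stop("a cluster is annotated with more than one tissue")
    idx <- match(colnames(sce), cellClusters[[1L]])
    if (anyNA(idx))
        stop(sprintf("cell '%s' has no cluster annotation",
                     colnames(sce)[which(is.na(idx))[1L]]))
    cl <- cellClusters[[2L]][idx]
    tidx <- match(cl, clusterTissues[[1L]])
    if (anyNA(tidx))
        stop(sprintf("cluster '%s' has no tissue annotation",
                     cl[which(is.na(tidx))[1L]]))
    colData(sce)$cluster <- cl
    colData(sce)$tissue <- clusterTissues[[2L]][tidx]
    metadata(sce)$clusterToTissue <- stats::setNames(clusterTissues[[2L]],
                                                     clusterTissues[[1L]])
    sce
}

#' Log-normalize counts per cell
#'
#' Divides each cell's counts by its total, scales to `scaleTarget`, and
#' applies a zero-preserving shifted log, `log((pseudocount + x)/pseudocount)`
#' (equal to `log1p(x)` for the default pseudocount of 1). All-zero cells are
#' left all-zero and flagged with a warning, not dropped (set
#' `dropEmpty = TRUE` to drop them). The normalization record is stored in
#' `metadata(sce)$normalization`, so the transform is fully reproducible from
#' the raw counts.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param scaleTarget per-cell total after scaling (default 10,000).
#' @param pseudocount positive offset of the shifted log (default 1).
#' @param dropEmpty drop all-zero cells instead of retaining them flagged.
#' @return the SingleCellExperiment with a `logcounts` assay added.
#' @examples
#' sim <- simulateAtlas(nClusters = 2, nTissues = 1, cellsPerCluster = 5,
#'                      nGenes = 20, nDecoyPairs = 0, seed = 1)
#' sce <- normalizeAtlas(sim$sce)
#' SummarizedExperiment::assayNames(sce)
#' @export
normalizeAtlas <- function(sce, scaleTarget = 1e4, pseudocount = 1,
                           dropEmpty = FALSE) {
    stopifnot(scaleTarget > 0, pseudocount > 0)
    m <- counts(sce)
    totals <- Matrix::colSums(m)
    empty <- totals == 0
    if (any(empty)) {
        warning(sprintf("%d all-zero cell(s) %s: %s", sum(empty),
                        if (dropEmpty) "dropped" else "retained (flagged)",
                        paste(head(colnames(sce)[empty], 5L), collapse = ", ")))
        if (dropEmpty) {
            sce <- sce[, !empty]
            m <- counts(sce)
            totals <- totals[!empty]
            empty <- empty[!empty]
        }
    }
    sf <- ifelse(totals > 0, scaleTarget / totals, 0)
    if (is(m, "CsparseMatrix")) {
        ln <- m
        ln@x <- ln@x * rep.int(sf, diff(ln@p))
        ln@x <- log1p(ln@x / pseudocount)
    } else {
        ln <- log1p(sweep(as.matrix(m), 2L, sf, "*") / pseudocount)
    }
    assay(sce, "logcounts") <- ln
    metadata(sce)$normalization <- list(scaleTarget = scaleTarget,
                                        pseudocount = pseudocount,
                                        log = TRUE,
                                        emptyCells = colnames(sce)[empty])
    sce
}

.tissueOf <- function(sce) {
    td <- colData(sce)$tissue
    if (is.null(td))
        stop("atlas lacks tissue annotation; call addClusterAnnotation() first")
    td
}

#' Organ-level pseudobulk profiles
#'
#' Fallback for atlases without a companion bulk expression table: the entry
#' for (gene, organ) is the mean normalized expression of the gene over all
#' cells whose cluster maps to that organ.
#'
#' @param sce a normalized, annotated SingleCellExperiment.
#' @return a gene x organ numeric matrix.
#' @export
pseudobulkProfiles <- function(sce) {
    if (!"logcounts" %in% assayNames(sce))
        stop("atlas is not normalized; call normalizeAtlas() first")
    tissue <- .tissueOf(sce)
    organs <- unique(unname(metadata(sce)$clusterToTissue))
    if (is.null(organs)) organs <- unique(tissue)
    absent <- setdiff(organs, tissue)
    if (length(absent))
        stop(sprintf("organ '%s' has zero cells", absent[1L]))
    m <- logcounts(sce)
    out <- vapply(organs, function(org) {
        Matrix::rowMeans(m[, tissue == org, drop = FALSE])
    }, numeric(nrow(sce)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(sce))
    dimnames(out) <- list(rownames(sce), organs)
    out
}

#' Read / write a gene x organ bulk expression table
#'
#' The on-disk format is a TSV whose header row holds the organ identifiers
#' and whose first column holds gene identifiers; all values must be
#' non-negative.
#'
#' @param path TSV path.
#' @return `readBulkTable` returns a gene x organ numeric matrix.
#' @export
readBulkTable <- function(path) {
    tab <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE)
    m <- as.matrix(tab)
    if (anyDuplicated(colnames(m))) stop("duplicate organ id in bulk table")
    if (anyDuplicated(rownames(m))) stop("duplicate gene id in bulk table")
    if (any(m < 0)) stop("negative values in bulk table")
    m
}

#' @rdname readBulkTable
#' @param bulk a gene x organ matrix.
#' @export
writeBulkTable <- function(bulk, path) {
    df <- data.frame(gene_id = rownames(bulk), bulk, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Resolve the target tissue against bulk organ columns
#'
#' Organ ids are matched case-insensitively, with an optional explicit alias
#' map. An unmatched target tissue is an error; unmatched background organs
#' only warn.
#'
#' @param tissue tissue identifier from the cluster annotation.
#' @param organIds column names of the bulk table.
#' @param aliases named character vector mapping tissue ids to organ ids.
#' @return the matching element of `organIds`.
#' @keywords internal
.resolveOrgan <- function(tissue, organIds, aliases = NULL) {
    if (!is.null(aliases) && tissue %in% names(aliases))
        tissue <- unname(aliases[[tissue]])
    hit <- which(tolower(organIds) == tolower(tissue))
    if (length(hit) != 1L)
        stop(sprintf("target tissue '%s' not found among bulk organs (%s)",
                     tissue, paste(organIds, collapse = ", ")))
    organIds[hit]
}

#' Write a ranked-pairs report
#'
#' Writes the scored pairs plus run metadata (hyperparameters, config hash,
#' seed) as TSV and/or JSON. Output is deterministic: no timestamps, fixed
#' column order, full-precision numbers, so identical runs produce
#' byte-identical files.
#'
#' @param ranking a [PairRanking-class].
#' @param path output path (for `format = "both"`, `.tsv` and `.json` are
#'   appended to `path`).
#' @param format one of "tsv", "json", "both".
#' @return invisibly, the paths written.
#' @export
writeReport <- function(ranking, path, format = c("tsv", "json", "both")) {
    format <- match.arg(format)
    tab <- as.data.frame(pairTable(ranking))
    meta <- c(list(targetCluster = ranking@targetCluster,
                   targetTissue = ranking@targetTissue,
                   nClusters = ranking@nClusters,
                   hyperparams = .hpAsList(ranking@hyperparams)),
              ranking@diagnostics[intersect(c("seed", "configHash", "versions"),
                                            names(ranking@diagnostics))])
    paths <- character()
    if (format %in% c("tsv", "both")) {
        tsv <- if (format == "both") paste0(path, ".tsv") else path
        .writeAtomic(tsv, function(f) {
            con <- file(f, "w")
            on.exit(close(con))
            for (k in c("targetCluster", "targetTissue", "nClusters"))
                cat(sprintf("# %s=%s\n", k, meta[[k]]), file = con)
            cat(sprintf("# hyperparams=%s\n",
                        paste(names(meta$hyperparams),
                              unlist(meta$hyperparams), sep = "=",
                              collapse = ";")), file = con)
            for (k in intersect(c("seed", "configHash"), names(meta)))
                cat(sprintf("# %s=%s\n", k, meta[[k]]), file = con)
            write.table(tab, con, sep = "\t", quote = FALSE,
                        row.names = FALSE)
        })
        paths <- c(paths, tsv)
    }
    if (format %in% c("json", "both")) {
        js <- if (format == "both") paste0(path, ".json") else path
        .writeAtomic(js, function(f) {
            jsonlite::write_json(list(metadata = meta, pairs = tab), f,
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        })
        paths <- c(paths, js)
    }
    invisible(paths)
}

.hpAsList <- function(hp) {
    sl <- methods::slotNames(hp)
    stats::setNames(lapply(sl, function(s) slot(hp, s)), sl)
}
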