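#' @importFrom stats var pt p.adjust setNames
NULL

#' Tau organ-specificity index
#'
#' Tau over an expression profile across N organs:
#' \deqn{\tau = \sum_i (1 - \hat x_i) / (N - 1), \qquad \hat x_i = x_i / \max_j x_j}
#' Tau is 0 for a uniform positive profile, 1 when exactly one organ is
#' nonzero, and is invariant to positive rescaling of the profile. The profile
#' is used as given (linear scale); see the vignette for why no log transform
#' is applied first.
#'
#' @param profile numeric vector (length >= 2) of non-negative expression
#'   values, one per organ.
#' @return Tau in \[0, 1\], or `NA` for an all-zero profile (such genes are
#'   excluded from candidacy rather than erroring).
#' @examples
#' computeTau(c(100, 0, 0, 0, 0))  # 1
#' computeTau(c(7, 7, 7))          # 0
#' computeTau(c(10, 5, 0, 0))      # 0.8333...
#' @export
computeTau <- function(profile) {
    stopifnot(is.numeric(profile), length(profile) >= 2L)
    if (any(profile < 0)) stop("Tau requires a non-negative profile")
    mx <- max(profile)
    if (mx == 0) return(NA_real_)
    sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Within-cluster dispersion (variance / mean)
#'
#' Sample variance (n - 1 denominator) divided by the mean of a gene's raw
#' counts across the cells of one cluster. Approximately 1 under Poisson
#' noise; overdispersed genes exceed 1. A mean of zero is defined as
#' dispersion 0.
#'
#' @param values numeric vector of raw counts for one gene over the cells of
#'   a cluster (length >= 2).
#' @return non-negative dispersion.
#' @examples
#' computeDispersion(c(4, 4, 4, 4))  # 0
#' computeDispersion(c(0, 1, 2, 3))  # 1.111...
#' @export
computeDispersion <- function(values) {
    if (length(values) < 2L)
        stop("dispersion requires at least 2 cells in the cluster")
    m <- mean(values)
    if (m == 0) return(0)
    var(values) / m
}

# Welch two-sample t with explicit conventions for degenerate variances:
# both variances zero with equal means -> t = 0, p = 1; zero variance with
# unequal means -> t = +/-Inf, p = 0 (stats::t.test errors on these).
.welch <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (nx < 2L || ny < 2L)
        stop("each group needs at least 2 observations")
    mx <- mean(x); my <- mean(y)
    vx <- var(x); vy <- var(y)
    if (vx == 0 && vy == 0) {
        if (mx == my) return(c(t = 0, p = 1, df = NA_real_))
        return(c(t = sign(mx - my) * Inf, p = 0, df = NA_real_))
    }
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    c(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' One-vs-rest Welch t-test for a gene
#'
#' Welch (unequal-variance) two-sample t-test of a gene's normalized
#' expression in the target cluster's cells against all other cells,
#' two-sided.
#'
#' @param sce a normalized, annotated SingleCellExperiment.
#' @param geneId gene to test.
#' @param target target cluster id.
#' @return named numeric vector `c(t, p, df)`. Degenerate inputs follow fixed
#'   conventions: zero variance in both groups with equal means gives
#'   `t = 0, p = 1`; with unequal means `t = +/-Inf, p = 0`.
#' @export
oneVsRestTTest <- function(sce, geneId, target) {
    if (!geneId %in% rownames(sce)) stop(sprintf("unknown gene '%s'", geneId))
    inT <- colData(sce)$cluster == target
    if (sum(inT) < 2L || sum(!inT) < 2L)
        stop("target cluster and its complement each need >= 2 cells")
    v <- as.numeric(logcounts(sce)[geneId, ])
    .welch(v[inT], v[!inT])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, each >= its raw p, <= 1).
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Binarized marker calls per gene and cluster
#'
#' A gene is a "potential marker" of a cluster when the fraction of cells in
#' the cluster with nonzero expression is at least `fOn` and the mean
#' normalized expression in the cluster is at least `eMin` (both thresholds
#' closed).
#'
#' @param sce a normalized, annotated SingleCellExperiment.
#' @param hp a [MarkerHyperparams-class] supplying `fOn` and `eMin`.
#' @return a logical gene x cluster matrix with attribute `thresholds`.
#' @export
binarizeMarkers <- function(sce, hp = markerHyperparams()) {
    m <- logcounts(sce)
    cl <- colData(sce)$cluster
    clusters <- sort(unique(cl))
    fracOn <- vapply(clusters, function(cc)
        Matrix::rowMeans(m[, cl == cc, drop = FALSE] > 0), numeric(nrow(m)))
    meanEx <- vapply(clusters, function(cc)
        Matrix::rowMeans(m[, cl == cc, drop = FALSE]), numeric(nrow(m)))
    calls <- fracOn >= hp@fOn & meanEx >= hp@eMin
    dimnames(calls) <- list(rownames(sce), clusters)
    attr(calls, "thresholds") <- c(fOn = hp@fOn, eMin = hp@eMin)
    calls
}

#' Per-gene selection metrics for a target cluster
#'
#' Computes, for every gene of the atlas: organ-specificity Tau from the bulk
#' (or pseudobulk) profile; within-target-cluster dispersion of raw counts;
#' one-vs-rest Welch t statistic with BH-adjusted p; expressing fraction and
#' group means; and the bulk expression in the target organ (log1p scale,
#' the scale on which `bulkMin` is applied).
#'
#' @param sce a normalized, annotated SingleCellExperiment.
#' @param bulk gene x organ bulk matrix, e.g. from [readBulkTable()] or
#'   [pseudobulkProfiles()]. Genes absent from the bulk table get `NA` Tau and
#'   bulk values (and so cannot become candidates).
#' @param target target cluster id.
#' @param organAliases optional named map from tissue ids to bulk organ ids.
#' @return a [S4Vectors::DataFrame] with one row per gene: `tau`,
#'   `dispersion`, `tStat`, `pT`, `qT`, `fracOnTarget`, `meanTarget`,
#'   `meanRest`, `bulkTarget`.
#' @export
geneMetrics <- function(sce, bulk, target, organAliases = NULL) {
    cl <- colData(sce)$cluster
    if (!target %in% cl) stop(sprintf("unknown target cluster '%s'", target))
    tissue <- .tissueOf(sce)
    targetTissue <- unique(tissue[cl == target])
    stopifnot(length(targetTissue) == 1L)
    organ <- .resolveOrgan(targetTissue, colnames(bulk), organAliases)
    missingOrg <- setdiff(unique(tissue), c(colnames(bulk), names(organAliases)))
    missingOrg <- missingOrg[!tolower(missingOrg) %in% tolower(colnames(bulk))]
    if (length(missingOrg))
        warning(sprintf("background organ(s) absent from bulk table: %s",
                        paste(missingOrg, collapse = ", ")))

    bidx <- match(rownames(sce), rownames(bulk))
    tau <- rep(NA_real_, nrow(sce))
    bulkTarget <- rep(NA_real_, nrow(sce))
    has <- !is.na(bidx)
    if (any(has)) {
        bm <- bulk[bidx[has], , drop = FALSE]
        tau[has] <- apply(bm, 1L, computeTau)
        bulkTarget[has] <- log1p(bm[, organ])
    }

    inT <- cl == target
    if (sum(inT) < 2L || sum(!inT) < 2L)
        stop("target cluster and its complement each need >= 2 cells")
    rawT <- counts(sce)[, inT, drop = FALSE]
    muRaw <- Matrix::rowMeans(rawT)
    dispersion <- ifelse(muRaw == 0, 0, .rowVars(rawT) / muRaw)

    ln <- logcounts(sce)
    lt <- ln[, inT, drop = FALSE]
    lr <- ln[, !inT, drop = FALSE]
    nT <- ncol(lt); nR <- ncol(lr)
    mT <- Matrix::rowMeans(lt); mR <- Matrix::rowMeans(lr)
    vT <- .rowVars(lt); vR <- .rowVars(lr)
    se2 <- vT / nT + vR / nR
    tStat <- ifelse(se2 > 0, (mT - mR) / sqrt(se2),
                    ifelse(mT == mR, 0, sign(mT - mR) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((vT / nT)^2 / (nT - 1) + (vR / nR)^2 / (nR - 1)),
                 NA_real_)
    pT <- ifelse(is.finite(tStat) & se2 > 0, 2 * pt(-abs(tStat), df),
                 ifelse(tStat == 0, 1, 0))

    DataFrame(row.names = rownames(sce),
              tau = tau,
              dispersion = as.numeric(dispersion),
              tStat = as.numeric(tStat),
              pT = as.numeric(pT),
              qT = bhAdjust(as.numeric(pT)),
              fracOnTarget = Matrix::rowMeans(lt > 0),
              meanTarget = as.numeric(mT),
              meanRest = as.numeric(mR),
              bulkTarget = bulkTarget)
}

#' Candidate genes by three-way filter intersection
#'
#' Genes satisfying all of: Tau at least `tauMin`; dispersion at most
#' `dispersionMax`; BH-adjusted one-vs-rest p at most `alpha` with the target
#' mean above the rest mean; and target-organ bulk expression at least
#' `bulkMin`. All thresholds are closed. The survivors are ordered by
#' ascending adjusted p, then descending Tau, then gene id, and truncated to
#' `maxCandidates`.
#'
#' @param metrics per-gene metrics from [geneMetrics()].
#' @param hp a [MarkerHyperparams-class].
#' @return a list with `genes` (ordered candidate ids; empty when nothing
#'   passes — this is a result, not an error), `filterCounts` (per-filter
#'   survivor counts for diagnosis), and `table` (the metrics rows of the
#'   candidates).
#' @export
candidateGenes <- function(metrics, hp = markerHyperparams()) {
    gene <- rownames(metrics)
    passTau <- !is.na(metrics$tau) & metrics$tau >= hp@tauMin
    passDisp <- metrics$dispersion <= hp@dispersionMax
    passT <- !is.na(metrics$qT) & metrics$qT <= hp@alpha &
        metrics$meanTarget > metrics$meanRest
    passBulk <- !is.na(metrics$bulkTarget) & metrics$bulkTarget >= hp@bulkMin
    all4 <- passTau & passDisp & passT & passBulk
    ord <- order(metrics$qT[all4], -metrics$tau[all4], gene[all4])
    genes <- gene[all4][ord]
    if (length(genes) > hp@maxCandidates)
        genes <- genes[seq_len(hp@maxCandidates)]
    list(genes = genes,
         filterCounts = c(tau = sum(passTau), dispersion = sum(passDisp),
                          ttest = sum(passT), bulk = sum(passBulk),
                          intersection = sum(all4),
                          retained = length(genes)),
         table = metrics[genes, , drop = FALSE])
}
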