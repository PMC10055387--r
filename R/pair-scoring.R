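#' @importFrom stats pwilcox pnorm
NULL

#' Enumerate all unordered candidate pairs
#'
#' @param genes character vector of candidate gene ids.
#' @return a two-column character matrix (`geneA`, `geneB`) of all C(n, 2)
#'   pairs with `geneA < geneB`; zero rows when fewer than two candidates.
#' @export
enumeratePairs <- function(genes) {
    genes <- sort(unique(as.character(genes)))
    if (length(genes) < 2L)
        return(matrix(character(), ncol = 2L,
                      dimnames = list(NULL, c("geneA", "geneB"))))
    cmb <- utils::combn(genes, 2L)
    matrix(c(cmb[1L, ], cmb[2L, ]), ncol = 2L,
           dimnames = list(NULL, c("geneA", "geneB")))
}

#' Off-target cluster count for a pair
#'
#' Number of non-target clusters in which both genes of the pair are called
#' potential markers.
#'
#' @param geneA,geneB gene ids (order irrelevant).
#' @param markers logical gene x cluster matrix from [binarizeMarkers()].
#' @param target target cluster id.
#' @return non-negative integer count.
#' @export
countOffTarget <- function(geneA, geneB, markers, target) {
    for (g in c(geneA, geneB))
        if (!g %in% rownames(markers))
            stop(sprintf("unknown gene '%s' in marker matrix", g))
    if (!target %in% colnames(markers))
        stop(sprintf("unknown target cluster '%s'", target))
    both <- markers[geneA, ] & markers[geneB, ]
    sum(both[colnames(markers) != target])
}

#' Metagene of a gene pair
#'
#' Per-cell arithmetic mean of the two genes' normalized expression values;
#' a single composite marker signal for the pair.
#'
#' @param geneA,geneB gene ids.
#' @param sce a normalized SingleCellExperiment.
#' @return numeric vector, one value per cell.
#' @export
metageneValues <- function(geneA, geneB, sce) {
    for (g in c(geneA, geneB))
        if (!g %in% rownames(sce)) stop(sprintf("unknown gene '%s'", g))
    m <- logcounts(sce)
    (as.numeric(m[geneA, ]) + as.numeric(m[geneB, ])) / 2
}

#' Wilcoxon rank-sum test of a per-cell signal, target vs rest
#'
#' Computes the Mann-Whitney U statistic of the target group with midranks
#' for ties. The two-sided p-value is exact (via the null rank-sum
#' distribution) when both groups have at most 8 observations and there are
#' no ties; otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param values numeric per-cell signal (e.g. from [metageneValues()]).
#' @param inTarget logical vector, `TRUE` for target-cluster cells.
#' @return named numeric vector `c(u, p)`; `u` is U for the target group, so
#'   `u / (n1 * n2)` is the AUROC of the signal for the target.
#' @examples
#' wilcoxonRankSum(c(1.2, 3.4, 5.6, 0.1, 0.2, 0.3),
#'                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))  # u = 9, p = 0.1
#' @export
wilcoxonRankSum <- function(values, inTarget) {
    stopifnot(length(values) == length(inTarget))
    n1 <- sum(inTarget); n2 <- sum(!inTarget)
    if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
    r <- rank(values)
    u <- sum(r[inTarget]) - n1 * (n1 + 1) / 2
    tieCounts <- table(values)
    hasTies <- any(tieCounts > 1L)
    if (!hasTies && n1 <= 8L && n2 <= 8L) {
        lower <- pwilcox(u, n1, n2)
        upper <- 1 - pwilcox(u - 1, n1, n2)
        p <- min(1, 2 * min(lower, upper))
    } else {
        n <- n1 + n2
        mu <- n1 * n2 / 2
        tieTerm <- sum(tieCounts^3 - tieCounts) / (n * (n - 1))
        sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm)
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
            p <- min(1, 2 * pnorm(-abs(z)))
        }
    }
    c(u = as.numeric(u), p = p)
}

#' Combined score of a candidate pair
#'
#' Weighted combination of the pair's metagene AUROC, its off-target cluster
#' count (normalized by the number of non-target clusters so weights transfer
#' across atlases), and the smaller of the two genes' Tau values:
#' \deqn{S = w_{auc} \cdot AUROC - w_{off} \cdot K_{off}/(n_{clusters}-1)
#'       + w_{tau} \cdot \min(\tau_a, \tau_b)}
#'
#' @param kOff off-target cluster count.
#' @param auroc metagene AUROC in \[0, 1\].
#' @param tauMinPair min of the two genes' Tau.
#' @param hp a [MarkerHyperparams-class] supplying the weights.
#' @param nClusters number of clusters in the atlas (>= 2).
#' @return the combined score (higher is better).
#' @export
scorePair <- function(kOff, auroc, tauMinPair, hp = markerHyperparams(),
                      nClusters) {
    if (nClusters < 2L) stop("scoring requires at least 2 clusters")
    hp@wAuc * auroc - hp@wOff * (kOff / (nClusters - 1L)) +
        hp@wTau * tauMinPair
}

#' Rank all candidate gene pairs for a target cluster
#'
#' The full selection pipeline after normalization: per-gene metrics,
#' three-way candidate filtering, marker binarization, pair enumeration,
#' per-pair off-target counting and metagene Wilcoxon testing, combined
#' scoring, and deterministic ranking (descending score; ties by ascending
#' off-target count, then lexicographic pair identity).
#'
#' @param sce a normalized, annotated SingleCellExperiment.
#' @param bulk gene x organ bulk matrix ([readBulkTable()]) or `NULL` to fall
#'   back to [pseudobulkProfiles()].
#' @param target target cluster id.
#' @param hp a [MarkerHyperparams-class].
#' @param organAliases optional tissue-to-organ alias map.
#' @return a [PairRanking-class]; empty (zero rows, with per-filter survivor
#'   counts in its diagnostics) when fewer than two candidate genes survive.
#' @examples
#' sim <- simulateAtlas(seed = 7)
#' sce <- normalizeAtlas(sim$sce)
#' rk <- rankPairs(sce, sim$bulk, target = targetCluster(sim$truth))
#' head(pairTable(rk))
#' @export
rankPairs <- function(sce, bulk = NULL, target, hp = markerHyperparams(),
                      organAliases = NULL) {
    if (is.null(bulk)) bulk <- pseudobulkProfiles(sce)
    cl <- colData(sce)$cluster
    clusters <- sort(unique(cl))
    nClusters <- length(clusters)
    tissue <- .tissueOf(sce)
    targetTissue <- unique(tissue[cl == target])

    metrics <- geneMetrics(sce, bulk, target, organAliases)
    cand <- candidateGenes(metrics, hp)
    markers <- binarizeMarkers(sce, hp)

    genes <- cand$genes
    if (hp@requireTargetCall && length(genes))
        genes <- genes[markers[genes, target]]

    diag <- list(filterCounts = cand$filterCounts,
                 candidates = cand$genes,
                 candidatesAfterTargetCall = genes)

    emptyTab <- DataFrame(rank = integer(), geneA = character(),
                          geneB = character(), kOff = integer(),
                          uStat = numeric(), pU = numeric(),
                          auroc = numeric(), tauMinPair = numeric(),
                          score = numeric())
    if (length(genes) < 2L) {
        return(new("PairRanking", pairs = emptyTab,
                   targetCluster = target, targetTissue = targetTissue,
                   nClusters = as.integer(nClusters), hyperparams = hp,
                   diagnostics = diag))
    }

    pairs <- enumeratePairs(genes)
    inT <- cl == target
    ln <- as.matrix(logcounts(sce)[genes, , drop = FALSE])
    tauG <- setNames(metrics$tau, rownames(metrics))
    n1 <- sum(inT); n2 <- sum(!inT)

    nP <- nrow(pairs)
    kOff <- integer(nP); uStat <- numeric(nP); pU <- numeric(nP)
    for (i in seq_len(nP)) {
        a <- pairs[i, 1L]; b <- pairs[i, 2L]
        kOff[i] <- countOffTarget(a, b, markers, target)
        mg <- (ln[a, ] + ln[b, ]) / 2
        w <- wilcoxonRankSum(mg, inT)
        uStat[i] <- w[["u"]]; pU[i] <- w[["p"]]
    }
    auroc <- uStat / (n1 * n2)
    tauMinPair <- pmin(tauG[pairs[, 1L]], tauG[pairs[, 2L]])
    score <- scorePair(kOff, auroc, tauMinPair, hp, nClusters)

    ord <- order(-score, kOff, pairs[, 1L], pairs[, 2L])
    tab <- DataFrame(rank = seq_len(nP),
                     geneA = unname(pairs[ord, 1L]),
                     geneB = unname(pairs[ord, 2L]),
                     kOff = kOff[ord], uStat = uStat[ord], pU = pU[ord],
                     auroc = auroc[ord],
                     tauMinPair = as.numeric(tauMinPair[ord]),
                     score = as.numeric(score[ord]))
    new("PairRanking", pairs = tab, targetCluster = target,
        targetTissue = targetTissue, nClusters = as.integer(nClusters),
        hyperparams = hp, diagnostics = diag)
}
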