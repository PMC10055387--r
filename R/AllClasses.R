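#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Hyperparameters for marker-pair selection
#'
#' Bundles every tunable threshold and weight of the selection pipeline.
#' Candidate genes must satisfy \code{tau >= tauMin}, \code{dispersion <=
#' dispersionMax}, BH-adjusted one-vs-rest p \code{<= alpha} (with target mean
#' above rest mean), and organ-level bulk expression \code{>= bulkMin}
#' (log1p scale). A gene is called a "potential marker" of a cluster when the
#' fraction of expressing cells is \code{>= fOn} and its mean log-normalized
#' expression is \code{>= eMin}. Pairs are scored as
#' \code{wAuc * AUROC - wOff * K_off/(n_clusters - 1) + wTau * min(tau_a, tau_b)}.
#'
#' All thresholds are closed (ties pass). Defaults were calibrated with
#' [gridSearch()] on synthetic atlases (see the package vignette); every run
#' records the values used, so results are reproducible.
#'
#' @slot tauMin minimum organ-specificity Tau in \[0, 1\].
#' @slot dispersionMax maximum within-target-cluster dispersion
#'   (variance/mean of raw counts).
#' @slot alpha BH-adjusted p-value cutoff for the one-vs-rest Welch t-test.
#' @slot bulkMin minimum bulk expression in the target organ, on the
#'   log1p scale.
#' @slot fOn minimum fraction of expressing (nonzero) cells for a marker call.
#' @slot eMin minimum mean log-normalized expression for a marker call.
#' @slot wAuc,wOff,wTau non-negative weights of the combined pair score.
#' @slot maxCandidates cap on the number of candidate genes carried into
#'   pair enumeration.
#' @slot requireTargetCall if \code{TRUE} (default), both genes of a scored
#'   pair must themselves be called markers of the target cluster.
#'
#' @seealso [markerHyperparams()] for the user-facing constructor.
#' @export
setClass("MarkerHyperparams",
    representation(
        tauMin = "numeric",
        dispersionMax = "numeric",
        alpha = "numeric",
        bulkMin = "numeric",
        fOn = "numeric",
        eMin = "numeric",
        wAuc = "numeric",
        wOff = "numeric",
        wTau = "numeric",
        maxCandidates = "integer",
        requireTargetCall = "logical"
    ),
    prototype(
        tauMin = 0.6,
        dispersionMax = 5.0,
        alpha = 0.05,
        bulkMin = 1.0,
        fOn = 0.10,
        eMin = 4.0,
        wAuc = 1.0,
        wOff = 1.0,
        wTau = 0.5,
        maxCandidates = 50L,
        requireTargetCall = TRUE
    )
)

setValidity("MarkerHyperparams", function(object) {
    msg <- character()
    num1 <- c("tauMin", "dispersionMax", "alpha", "bulkMin", "fOn", "eMin",
              "wAuc", "wOff", "wTau")
    for (s in num1) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(msg) == 0L) {
        if (object@tauMin < 0 || object@tauMin > 1)
            msg <- c(msg, "'tauMin' must be in [0, 1]")
        if (object@fOn < 0 || object@fOn > 1)
            msg <- c(msg, "'fOn' must be in [0, 1]")
        if (object@alpha < 0 || object@alpha > 1)
            msg <- c(msg, "'alpha' must be in [0, 1]")
        if (object@dispersionMax < 0)
            msg <- c(msg, "'dispersionMax' must be >= 0")
        if (object@wAuc < 0 || object@wOff < 0 || object@wTau < 0)
            msg <- c(msg, "weights must be non-negative")
        if (object@wAuc + object@wOff + object@wTau <= 0)
            msg <- c(msg, "at least one weight must be > 0")
        if (length(object@maxCandidates) != 1L || is.na(object@maxCandidates) ||
            object@maxCandidates < 1L)
            msg <- c(msg, "'maxCandidates' must be a positive integer")
        if (length(object@requireTargetCall) != 1L ||
            is.na(object@requireTargetCall))
            msg <- c(msg, "'requireTargetCall' must be TRUE or FALSE")
    }
    if (length(msg)) msg else TRUE
})

#' Construct selection hyperparameters
#'
#' @param tauMin,dispersionMax,alpha,bulkMin,fOn,eMin,wAuc,wOff,wTau,maxCandidates,requireTargetCall
#'   see the slot documentation in [MarkerHyperparams-class]. Any argument left
#'   missing keeps its default.
#' @return a validated [MarkerHyperparams-class] object.
#' @examples
#' hp <- markerHyperparams(tauMin = 0.5, wTau = 1)
#' hp
#' @export
markerHyperparams <- function(tauMin = 0.6, dispersionMax = 5.0, alpha = 0.05,
                              bulkMin = 1.0, fOn = 0.10, eMin = 4.0,
                              wAuc = 1.0, wOff = 1.0, wTau = 0.5,
                              maxCandidates = 50L, requireTargetCall = TRUE) {
    new("MarkerHyperparams",
        tauMin = as.numeric(tauMin), dispersionMax = as.numeric(dispersionMax),
        alpha = as.numeric(alpha), bulkMin = as.numeric(bulkMin),
        fOn = as.numeric(fOn), eMin = as.numeric(eMin),
        wAuc = as.numeric(wAuc), wOff = as.numeric(wOff),
        wTau = as.numeric(wTau),
        maxCandidates = as.integer(maxCandidates),
        requireTargetCall = isTRUE(requireTargetCall))
}

#' Ranked marker gene pairs for one target cluster
#'
#' The result of [rankPairs()]: one row per scored pair, ordered by descending
#' combined score, with ties broken by ascending off-target count and then by
#' the lexicographic (geneA, geneB) pair identity, so the ranking is fully
#' deterministic for fixed inputs and configuration.
#'
#' @slot pairs a [S4Vectors::DataFrame] with columns \code{rank}, \code{geneA},
#'   \code{geneB} (geneA < geneB), \code{kOff}, \code{uStat}, \code{pU},
#'   \code{auroc}, \code{tauMinPair}, \code{score}.
#' @slot targetCluster,targetTissue identity of the cluster being marked and
#'   its containing organ.
#' @slot nClusters number of clusters in the atlas (used to normalize kOff).
#' @slot hyperparams the [MarkerHyperparams-class] used.
#' @slot diagnostics list with candidate-filter survivor counts, the candidate
#'   gene list, and run provenance (seed, config hash) when produced by
#'   [cmdRank()].
#' @export
setClass("PairRanking",
    representation(
        pairs = "DataFrame",
        targetCluster = "character",
        targetTissue = "character",
        nClusters = "integer",
        hyperparams = "MarkerHyperparams",
        diagnostics = "list"
    )
)

setValidity("PairRanking", function(object) {
    need <- c("rank", "geneA", "geneB", "kOff", "uStat", "pU", "auroc",
              "tauMinPair", "score")
    msg <- character()
    if (!all(need %in% colnames(object@pairs)))
        msg <- c(msg, paste("pairs table must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(object@pairs) > 0L) {
        if (any(object@pairs$geneA >= object@pairs$geneB))
            msg <- c(msg, "geneA must precede geneB lexicographically")
        if (is.unsorted(-object@pairs$score))
            msg <- c(msg, "pairs must be ordered by descending score")
        if (any(object@pairs$auroc < 0 | object@pairs$auroc > 1))
            msg <- c(msg, "auroc must lie in [0, 1]")
        if (any(object@pairs$kOff < 0 |
                object@pairs$kOff > object@nClusters - 1L))
            msg <- c(msg, "kOff must lie in [0, nClusters - 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated atlas
#'
#' Returned by [simulateAtlas()] alongside the counts: the identity of the
#' planted exclusive pair (whose true off-target set is empty), the decoy
#' pairs, and each decoy's true off-target cluster set.
#'
#' @slot plantedPair character(2), the exclusively co-marking gene pair.
#' @slot decoyPairs list of character(2) decoy pairs.
#' @slot decoyOfftargets list (parallel to \code{decoyPairs}) of the non-target
#'   cluster ids in which each decoy pair is also co-expressed.
#' @slot targetCluster,targetTissue the planted pair's home cluster and organ.
#' @export
setClass("AtlasTruth",
    representation(
        plantedPair = "character",
        decoyPairs = "list",
        decoyOfftargets = "list",
        targetCluster = "character",
        targetTissue = "character"
    )
)

setValidity("AtlasTruth", function(object) {
    msg <- character()
    if (length(object@plantedPair) != 2L)
        msg <- c(msg, "plantedPair must name exactly two genes")
    if (length(object@decoyPairs) != length(object@decoyOfftargets))
        msg <- c(msg, "decoyPairs and decoyOfftargets must be parallel lists")
    if (length(msg)) msg else TRUE
})

#' An in-frame knock-in homology-arm design
#'
#' Coordinates and sequences of the left/right homology arms flanking an
#' insertion point inside an early codon of a coding sequence. The arms are
#' reported in coding-strand orientation; genomic coordinates are 0-based
#' half-open on the forward strand. By construction the left arm ends on the
#' first nucleotide of the chosen codon, that nucleotide is never a thymine
#' (which would complete a TAG stop at the junction), and
#' \code{leftArm + rightArm} is the contiguous coding-strand genomic sequence
#' spanning the split point. The two nucleotides needed to restore the split
#' codon's frame (\code{codonRemainder}) are reported as metadata for the
#' cassette, not designed here.
#'
#' @slot geneId,transcriptId identifiers from the annotation.
#' @slot contig sequence name the design lies on.
#' @slot strand "+" or "-".
#' @slot codonIndex 1-based codon index within the CDS whose first nucleotide
#'   ends the left arm.
#' @slot insertionPoint 0-based forward-strand coordinate of the boundary
#'   immediately after the codon's first nucleotide (in coding direction).
#' @slot armLength length of each arm in bp (default 200).
#' @slot leftArm,rightArm [Biostrings::DNAString] arms, coding orientation.
#' @slot leftArmRange,rightArmRange [GenomicRanges::GRanges] of the arms on the
#'   forward strand (0-based half-open coordinates stored in metadata columns
#'   \code{start0}/\code{end0} alongside the usual 1-based ranges).
#' @slot codonRemainder the 2 nt of the split codon that the inserted cassette
#'   must restore.
#' @slot diagnostics named logical vector of rule checks.
#' @export
setClass("ArmDesign",
    representation(
        geneId = "character",
        transcriptId = "character",
        contig = "character",
        strand = "character",
        codonIndex = "integer",
        insertionPoint = "integer",
        armLength = "integer",
        leftArm = "DNAString",
        rightArm = "DNAString",
        leftArmRange = "GRanges",
        rightArmRange = "GRanges",
        codonRemainder = "character",
        diagnostics = "logical"
    )
)

setValidity("ArmDesign", function(object) {
    msg <- character()
    L <- object@armLength
    if (length(object@leftArm) != L || length(object@rightArm) != L)
        msg <- c(msg, "both arms must have length exactly 'armLength'")
    jn <- as.character(Biostrings::subseq(object@leftArm, start = L, width = 1L))
    if (identical(jn, "T"))
        msg <- c(msg, "left arm must not end in a thymine (TAG stop at junction)")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (object@codonIndex < 2L)
        msg <- c(msg, "codonIndex must be >= 2 (never split the start codon)")
    if (nchar(object@codonRemainder) != 2L)
        msg <- c(msg, "codonRemainder must be the 2 nt completing the codon")
    if (length(msg)) msg else TRUE
})
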