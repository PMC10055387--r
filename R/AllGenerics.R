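#' @include AllClasses.R
NULL

#' Accessors for pairmark S4 objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x a [PairRanking-class], [AtlasTruth-class] or [ArmDesign-class].
#' @return `pairTable` returns the [S4Vectors::DataFrame] of scored pairs;
#'   `hyperParams` the [MarkerHyperparams-class] used; `targetCluster` /
#'   `targetTissue` the target identities; `plantedPair` the simulated true
#'   pair; `leftArm` / `rightArm` the [Biostrings::DNAString] homology arms;
#'   `armRanges` a 2-row [GenomicRanges::GRanges] of the arms on the forward
#'   strand; `designDiagnostics` the named logical rule checks.
#' @name pairmark-accessors
#' @aliases pairTable hyperParams targetCluster targetTissue plantedPair
#'   leftArm rightArm armRanges designDiagnostics
NULL

#' @rdname pairmark-accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairmark-accessors
#' @export
setGeneric("hyperParams", function(x) standardGeneric("hyperParams"))

#' @rdname pairmark-accessors
#' @export
setGeneric("targetCluster", function(x) standardGeneric("targetCluster"))

#' @rdname pairmark-accessors
#' @export
setGeneric("targetTissue", function(x) standardGeneric("targetTissue"))

#' @rdname pairmark-accessors
#' @export
setGeneric("plantedPair", function(x) standardGeneric("plantedPair"))

#' @rdname pairmark-accessors
#' @export
setGeneric("leftArm", function(x) standardGeneric("leftArm"))

#' @rdname pairmark-accessors
#' @export
setGeneric("rightArm", function(x) standardGeneric("rightArm"))

#' @rdname pairmark-accessors
#' @export
setGeneric("armRanges", function(x) standardGeneric("armRanges"))

#' @rdname pairmark-accessors
#' @export
setGeneric("designDiagnostics", function(x) standardGeneric("designDiagnostics"))

#' @rdname pairmark-accessors
#' @export
setMethod("pairTable", "PairRanking", function(x) x@pairs)

#' @rdname pairmark-accessors
#' @export
setMethod("hyperParams", "PairRanking", function(x) x@hyperparams)

#' @rdname pairmark-accessors
#' @export
setMethod("targetCluster", "PairRanking", function(x) x@targetCluster)

#' @rdname pairmark-accessors
#' @export
setMethod("targetTissue", "PairRanking", function(x) x@targetTissue)

#' @rdname pairmark-accessors
#' @export
setMethod("targetCluster", "AtlasTruth", function(x) x@targetCluster)

#' @rdname pairmark-accessors
#' @export
setMethod("targetTissue", "AtlasTruth", function(x) x@targetTissue)

#' @rdname pairmark-accessors
#' @export
setMethod("plantedPair", "AtlasTruth", function(x) x@plantedPair)

#' @rdname pairmark-accessors
#' @export
setMethod("leftArm", "ArmDesign", function(x) x@leftArm)

#' @rdname pairmark-accessors
#' @export
setMethod("rightArm", "ArmDesign", function(x) x@rightArm)

#' @rdname pairmark-accessors
#' @export
setMethod("armRanges", "ArmDesign", function(x) {
    gr <- c(x@leftArmRange, x@rightArmRange)
    names(gr) <- c("left", "right")
    gr
})

#' @rdname pairmark-accessors
#' @export
setMethod("designDiagnostics", "ArmDesign", function(x) x@diagnostics)

setMethod("show", "MarkerHyperparams", function(object) {
    cat("MarkerHyperparams\n")
    cat(sprintf("  filters: tau >= %g, dispersion <= %g, q <= %g, bulk >= %g\n",
                object@tauMin, object@dispersionMax, object@alpha,
                object@bulkMin))
    cat(sprintf("  marker call: frac on >= %g, mean expr >= %g\n",
                object@fOn, object@eMin))
    cat(sprintf("  score weights: auroc %g, off-target %g, tau %g\n",
                object@wAuc, object@wOff, object@wTau))
    cat(sprintf("  maxCandidates: %d, requireTargetCall: %s\n",
                object@maxCandidates, object@requireTargetCall))
})

setMethod("show", "PairRanking", function(object) {
    cat(sprintf("PairRanking: %d pair(s) for cluster '%s' (tissue '%s', %d clusters)\n",
                nrow(object@pairs), object@targetCluster, object@targetTissue,
                object@nClusters))
    if (nrow(object@pairs)) {
        show(utils::head(object@pairs, 5L))
        if (nrow(object@pairs) > 5L)
            cat(sprintf("  ... and %d more\n", nrow(object@pairs) - 5L))
    } else {
        surv <- object@diagnostics$filterCounts
        if (!is.null(surv))
            cat("  no pairs; filter survivors:",
                paste(names(surv), surv, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("show", "AtlasTruth", function(object) {
    cat(sprintf("AtlasTruth: planted pair %s + %s in cluster '%s' ('%s'); %d decoy pair(s)\n",
                object@plantedPair[1L], object@plantedPair[2L],
                object@targetCluster, object@targetTissue,
                length(object@decoyPairs)))
})

setMethod("show", "ArmDesign", function(object) {
    cat(sprintf("ArmDesign for %s (%s), strand %s\n", object@geneId,
                object@transcriptId, object@strand))
    cat(sprintf("  codon %d, insertion point %s:%d (0-based), arms %d bp\n",
                object@codonIndex, object@contig, object@insertionPoint,
                object@armLength))
    cat(sprintf("  junction base: %s (codon remainder %s)\n",
                as.character(Biostrings::subseq(object@leftArm,
                    start = object@armLength, width = 1L)),
                object@codonRemainder))
    cat(sprintf("  rule checks: %s\n",
                paste(names(object@diagnostics),
                      ifelse(object@diagnostics, "ok", "FAIL"),
                      sep = "=", collapse = ", ")))
})
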