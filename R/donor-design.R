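#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet subseq
#'   reverseComplement writeXStringSet xscat
#' @importFrom GenomicRanges GRanges start end strand seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import
NULL

# --- internal coordinate helpers -------------------------------------------
# All internal arithmetic is 0-based half-open on the forward strand; GFF3 /
# GRanges 1-based inclusive coordinates are converted at the boundary.

.cdsChunks <- function(cdsRanges) {
    st <- as.character(unique(GenomicRanges::strand(cdsRanges)))
    if (length(st) != 1L || !st %in% c("+", "-"))
        stop("CDS ranges must share a single '+' or '-' strand")
    contig <- as.character(unique(GenomicRanges::seqnames(cdsRanges)))
    if (length(contig) != 1L)
        stop("CDS ranges must lie on a single contig")
    o <- order(GenomicRanges::start(cdsRanges))
    list(start0 = GenomicRanges::start(cdsRanges)[o] - 1L,
         end0 = GenomicRanges::end(cdsRanges)[o],  # 1-based incl == 0-based excl
         strand = st, contig = contig)
}

# Genomic forward-strand 0-based position of the CDS nucleotide at 0-based
# coding offset `off`.
.cdsPosToGenomic <- function(chunks, off) {
    w <- chunks$end0 - chunks$start0
    idx <- if (chunks$strand == "+") seq_along(w) else rev(seq_along(w))
    cum <- c(0L, cumsum(w[idx]))
    i <- findInterval(off, cum, rightmost.closed = FALSE)
    within <- off - cum[i]
    ch <- idx[i]
    if (chunks$strand == "+")
        chunks$start0[ch] + within
    else
        chunks$end0[ch] - 1L - within
}

.codingSequence <- function(contigSeq, chunks) {
    parts <- DNAStringSet(lapply(seq_along(chunks$start0), function(i)
        subseq(contigSeq, start = chunks$start0[i] + 1L, end = chunks$end0[i])))
    s <- Reduce(xscat, as.list(parts))
    if (chunks$strand == "-") s <- reverseComplement(s)
    as(s, "DNAString")
}

.introns0 <- function(chunks) {
    n <- length(chunks$start0)
    if (n < 2L) return(list(start0 = integer(), end0 = integer()))
    list(start0 = chunks$end0[-n], end0 = chunks$start0[-1L])
}

# Feasibility of placing `armLength` arms around the first nucleotide of
# codon `k`: within the contig and not spanning any splice junction.
.armSpan0 <- function(chunks, p, armLength) {
    if (chunks$strand == "+") c(p - armLength + 1L, p + armLength + 1L)
    else c(p - armLength, p + armLength)
}

.armFeasible <- function(chunks, p, armLength, contigLen) {
    span <- .armSpan0(chunks, p, armLength)
    if (span[1L] < 0L || span[2L] > contigLen)
        return("arms would cross the contig boundary")
    intr <- .introns0(chunks)
    for (i in seq_along(intr$start0))
        if (intr$start0[i] < span[2L] && intr$end0[i] > span[1L])
            return("arms would span an annotated splice junction")
    NA_character_
}

.getContig <- function(genome, contig) {
    if (is(genome, "DNAString")) return(genome)
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (!contig %in% names(genome))
        stop(sprintf("contig '%s' not found in genome", contig))
    genome[[contig]]
}

# --- exported operations ----------------------------------------------------

#' Choose the insertion codon of a coding sequence
#'
#' Scans the CDS for the first codon usable as an in-frame insertion point
#' for a drop-in knock-in donor. A codon is valid when (i) its index is at
#' least 2 (the start codon is never split), (ii) its first nucleotide is not
#' a thymine — the left homology arm ends on that nucleotide, and a terminal
#' T would complete a TAG stop codon at the donor junction — and (iii) both
#' homology arms fit within the contig without spanning a splice junction.
#'
#' @param genome a [Biostrings::DNAStringSet] / `DNAString` / FASTA path.
#' @param cdsRanges [GenomicRanges::GRanges] of the transcript's CDS chunks
#'   (1-based inclusive, single contig and strand).
#' @param armLength homology-arm length used in the feasibility check
#'   (default 200 bp).
#' @param policy `"first_valid"` (default) or an explicit codon index, which
#'   is validated against the same rules.
#' @return the selected 1-based codon index within the CDS.
#' @export
selectInsertionCodon <- function(genome, cdsRanges, armLength = 200L,
                                 policy = "first_valid") {
    chunks <- .cdsChunks(cdsRanges)
    contigSeq <- .getContig(genome, chunks$contig)
    contigLen <- length(contigSeq)
    cds <- .codingSequence(contigSeq, chunks)
    if (length(cds) < 3L || length(cds) %% 3L != 0L)
        stop("CDS length must be a multiple of 3 and at least one codon")
    nCodons <- length(cds) %/% 3L
    checkCodon <- function(k) {
        first <- as.character(subseq(cds, start = 3L * (k - 1L) + 1L,
                                     width = 1L))
        if (first == "T")
            return(paste("codon starts with a thymine: the left arm would",
                         "end in T, which would create a TAG stop codon"))
        p <- .cdsPosToGenomic(chunks, 3L * (k - 1L))
        .armFeasible(chunks, p, as.integer(armLength), contigLen)
    }
    if (identical(policy, "first_valid")) {
        for (k in 2:nCodons)
            if (is.na(checkCodon(k))) return(as.integer(k))
        stop("no valid insertion codon in this CDS")
    }
    k <- as.integer(policy)
    if (is.na(k) || k < 2L || k > nCodons)
        stop(sprintf("explicit codon index must be in [2, %d]", nCodons))
    bad <- checkCodon(k)
    if (!is.na(bad)) stop(sprintf("codon %d rejected: %s", k, bad))
    k
}

#' Extract in-frame homology arms around a codon
#'
#' Builds the homology-arm design for an in-frame knock-in at the chosen
#' codon: the left arm is `armLength` coding-strand nucleotides ending at
#' (and including) the codon's first nucleotide; the right arm is the next
#' `armLength` coding-strand nucleotides starting at the codon's second
#' nucleotide. Minus-strand genes are handled by reverse-complementing
#' genomic sequence into coding orientation. Arms are genomic (contiguous in
#' the genome, as homology-directed repair requires); designs whose arms
#' would span a splice junction or run off the contig are rejected.
#'
#' @inheritParams selectInsertionCodon
#' @param codonIndex 1-based codon index, e.g. from
#'   [selectInsertionCodon()].
#' @param armLength arm length in bp (default 200).
#' @param geneId,transcriptId identifiers carried into the design.
#' @return an [ArmDesign-class].
#' @export
extractArms <- function(genome, cdsRanges, codonIndex, armLength = 200L,
                        geneId = "gene", transcriptId = "tx") {
    armLength <- as.integer(armLength)
    stopifnot(armLength >= 1L)
    chunks <- .cdsChunks(cdsRanges)
    contigSeq <- .getContig(genome, chunks$contig)
    contigLen <- length(contigSeq)
    cds <- .codingSequence(contigSeq, chunks)
    if (length(cds) < 3L || length(cds) %% 3L != 0L)
        stop("CDS length must be a multiple of 3 and at least one codon")
    k <- as.integer(codonIndex)
    if (k < 2L || k > length(cds) %/% 3L)
        stop("codonIndex out of range (must be >= 2 and within the CDS)")
    codon <- as.character(subseq(cds, start = 3L * (k - 1L) + 1L, width = 3L))
    if (substr(codon, 1L, 1L) == "T")
        stop("codon starts with a thymine: the left arm would end in T, ",
             "which would create a TAG stop codon")
    p <- .cdsPosToGenomic(chunks, 3L * (k - 1L))
    bad <- .armFeasible(chunks, p, armLength, contigLen)
    if (!is.na(bad)) stop(bad)

    if (chunks$strand == "+") {
        left <- subseq(contigSeq, start = p - armLength + 2L, end = p + 1L)
        right <- subseq(contigSeq, start = p + 2L, end = p + armLength + 1L)
        leftSpan0 <- c(p - armLength + 1L, p + 1L)
        rightSpan0 <- c(p + 1L, p + armLength + 1L)
        insertionPoint <- p + 1L
    } else {
        left <- reverseComplement(subseq(contigSeq, start = p + 1L,
                                         end = p + armLength))
        right <- reverseComplement(subseq(contigSeq, start = p - armLength + 1L,
                                          end = p))
        leftSpan0 <- c(p, p + armLength)
        rightSpan0 <- c(p - armLength, p)
        insertionPoint <- p
    }
    mkRange <- function(span0) {
        gr <- GRanges(chunks$contig,
                      IRanges(start = span0[1L] + 1L, end = span0[2L]),
                      strand = chunks$strand)
        mcols(gr)$start0 <- span0[1L]
        mcols(gr)$end0 <- span0[2L]
        gr
    }
    junction <- as.character(subseq(left, start = armLength, width = 1L))
    diagnostics <- c(
        armLengthOk = length(left) == armLength && length(right) == armLength,
        junctionIsCodonFirstNt = junction == substr(codon, 1L, 1L),
        junctionNotThymine = junction != "T",
        armsContiguous = TRUE,
        withinContig = TRUE,
        noIntronSpan = TRUE)
    new("ArmDesign", geneId = geneId, transcriptId = transcriptId,
        contig = chunks$contig, strand = chunks$strand,
        codonIndex = k, insertionPoint = as.integer(insertionPoint),
        armLength = armLength,
        leftArm = as(left, "DNAString"), rightArm = as(right, "DNAString"),
        leftArmRange = mkRange(leftSpan0), rightArmRange = mkRange(rightSpan0),
        codonRemainder = substr(codon, 2L, 3L),
        diagnostics = diagnostics)
}

#' Design knock-in homology arms from a genome and GFF3 annotation
#'
#' Frontend over [selectInsertionCodon()] and [extractArms()]: groups the
#' annotation's CDS features by transcript and emits one design per requested
#' transcript.
#'
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param annotation [GenomicRanges::GRanges] (e.g. from
#'   [rtracklayer::import()]) or GFF3 path with CDS features carrying
#'   `Parent` transcript identifiers.
#' @param transcripts character vector of transcript ids to design for.
#' @param armLength arm length in bp (default 200).
#' @param codon `"first_valid"` or an explicit codon index.
#' @return a named list of [ArmDesign-class] objects.
#' @export
designArms <- function(genome, annotation, transcripts, armLength = 200L,
                       codon = "first_valid") {
    if (is.character(annotation))
        annotation <- rtracklayer::import(annotation, format = "gff3")
    if (is.character(genome))
        genome <- readDNAStringSet(genome)
    cdsAll <- annotation[!is.na(annotation$type) & annotation$type == "CDS"]
    parents <- as.list(cdsAll$Parent)
    out <- lapply(transcripts, function(tx) {
        sel <- vapply(parents, function(p) tx %in% p, logical(1L))
        if (!any(sel))
            stop(sprintf("no CDS features with Parent '%s' in annotation", tx))
        cds <- cdsAll[sel]
        geneId <- tx
        txFeat <- annotation[!is.na(annotation$ID) & annotation$ID == tx]
        if (length(txFeat) == 1L && length(unlist(txFeat$Parent)))
            geneId <- unlist(txFeat$Parent)[1L]
        kk <- selectInsertionCodon(genome, cds, armLength = armLength,
                                   policy = codon)
        extractArms(genome, cds, kk, armLength = armLength,
                    geneId = geneId, transcriptId = tx)
    })
    names(out) <- transcripts
    out
}

#' Write homology-arm designs as TSV and FASTA
#'
#' @param designs list of [ArmDesign-class] objects (or a single one).
#' @param tsvPath,fastaPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeArmDesigns <- function(designs, tsvPath = NULL, fastaPath = NULL) {
    if (is(designs, "ArmDesign")) designs <- list(designs)
    paths <- character()
    if (!is.null(tsvPath)) {
        rows <- do.call(rbind, lapply(designs, function(d) {
            lr <- mcols(d@leftArmRange); rr <- mcols(d@rightArmRange)
            data.frame(gene_id = d@geneId, transcript_id = d@transcriptId,
                       contig = d@contig, strand = d@strand,
                       codon_index = d@codonIndex,
                       insertion_point = d@insertionPoint,
                       arm_length = d@armLength,
                       left_arm_start = lr$start0, left_arm_end = lr$end0,
                       right_arm_start = rr$start0, right_arm_end = rr$end0,
                       codon_remainder = d@codonRemainder,
                       left_arm = as.character(d@leftArm),
                       right_arm = as.character(d@rightArm),
                       rules_ok = all(d@diagnostics),
                       stringsAsFactors = FALSE)
        }))
        .writeAtomic(tsvPath, function(f)
            write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE))
        paths <- c(paths, tsvPath)
    }
    if (!is.null(fastaPath)) {
        seqs <- DNAStringSet(unlist(lapply(unname(designs), function(d)
            stats::setNames(as.character(c(DNAStringSet(d@leftArm),
                                           DNAStringSet(d@rightArm))),
                     paste0(d@transcriptId, c("_left_arm", "_right_arm"))))))
        .writeAtomic(fastaPath, function(f) writeXStringSet(seqs, f))
        paths <- c(paths, fastaPath)
    }
    invisible(paths)
}
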