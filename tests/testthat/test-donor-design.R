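# In-frame homology-arm design rules and coordinate arithmetic.

test_that("first_valid skips thymine-initial codons and the start codon", {
    # ATG GCC ...: codon 2 starts with G and is chosen
    fx <- plantCds(paste0("ATGGCC", strrep("GCA", 98)), contigLen = 2000L,
                   cdsStart0 = 800L)
    expect_identical(selectInsertionCodon(fx$genome, fx$cds), 2L)

    # codons 2..4 start with T, codon 5 starts with A -> codon 5
    cds5 <- paste0("ATG", "TTT", "TCT", "TGT", "ACC", strrep("GGA", 95))
    fx5 <- plantCds(cds5, contigLen = 2000L, cdsStart0 = 800L)
    expect_identical(selectInsertionCodon(fx5$genome, fx5$cds), 5L)

    # explicit codon whose first nucleotide is T is rejected, citing the stop
    expect_error(selectInsertionCodon(fx5$genome, fx5$cds, policy = 2),
                 "TAG stop codon")
    # explicit valid codon is accepted
    expect_identical(selectInsertionCodon(fx5$genome, fx5$cds, policy = 5L), 5L)
    # the start codon is never split
    expect_error(selectInsertionCodon(fx5$genome, fx5$cds, policy = 1),
                 "codon index")
    # a CDS that is not a codon multiple is rejected
    fxBad <- plantCds(strrep("A", 100), contigLen = 1000L, cdsStart0 = 400L)
    expect_error(selectInsertionCodon(fxBad$genome, fxBad$cds), "multiple of 3")
})

test_that("plus-strand arm coordinates match the stated arithmetic", {
    # 2 kb contig, CDS at forward 1000-1300 (0-based half-open), codon 2:
    # left arm 804-1004, right arm 1004-1204
    cds <- paste0("ATG", "GCC", strrep("CGA", 98))
    fx <- plantCds(cds, contigLen = 2000L, cdsStart0 = 1000L)
    d <- extractArms(fx$genome, fx$cds, codonIndex = 2L, armLength = 200L)
    gr <- armRanges(d)
    expect_identical(GenomicRanges::mcols(gr)$start0, c(804L, 1004L))
    expect_identical(GenomicRanges::mcols(gr)$end0, c(1004L, 1204L))
    expect_identical(d@insertionPoint, 1004L)

    contig <- as.character(fx$genome[[1]])
    expect_identical(as.character(leftArm(d)), substr(contig, 805, 1004))
    expect_identical(as.character(rightArm(d)), substr(contig, 1005, 1204))
    # left arm ends on the codon's first nucleotide (G of GCC), never T
    expect_identical(substr(as.character(leftArm(d)), 200, 200), "G")
    expect_identical(d@codonRemainder, "CC")
    # concatenation is the contiguous coding-strand genomic span
    expect_identical(paste0(as.character(leftArm(d)),
                            as.character(rightArm(d))),
                     substr(contig, 805, 1204))
    expect_true(all(designDiagnostics(d)[c("armLengthOk",
                                           "junctionIsCodonFirstNt",
                                           "junctionNotThymine")]))
})

test_that("minus-strand designs obey the strand-symmetry oracle", {
    cds <- paste0("ATG", "GAC", strrep("AGC", 60))
    for (seed in 1:3) {
        fwd <- plantCds(cds, contigLen = 1500L, cdsStart0 = 600L,
                        strand = "+", seed = seed)
        # the same gene encoded on the minus strand of the reverse-complement
        contigLen <- 1500L
        rcGenome <- Biostrings::DNAStringSet(
            Biostrings::reverseComplement(fwd$genome[[1]]))
        names(rcGenome) <- "chr1"
        # forward CDS occupies [600, 600 + len); on the revcomp contig it is
        # the minus strand at [contigLen - end, contigLen - start)
        len <- nchar(cds)
        revCds <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = contigLen - (600 + len) + 1L,
                             end = contigLen - 600L),
            strand = "-")
        dF <- extractArms(fwd$genome, fwd$cds, codonIndex = 3L,
                          armLength = 150L)
        dR <- extractArms(rcGenome, revCds, codonIndex = 3L, armLength = 150L)
        expect_identical(as.character(leftArm(dR)), as.character(leftArm(dF)))
        expect_identical(as.character(rightArm(dR)),
                         as.character(rightArm(dF)))
        # and the minus-strand arms are reverse complements of the forward
        # genomic windows they came from
        rc <- as.character(rcGenome[[1]])
        lr <- GenomicRanges::mcols(dR@leftArmRange)
        expect_identical(as.character(leftArm(dR)),
                         as.character(Biostrings::reverseComplement(
                             Biostrings::DNAString(
                                 substr(rc, lr$start0 + 1, lr$end0)))))
    }
})

test_that("arms crossing contig ends or splice junctions are rejected", {
    cds <- paste0("ATG", "GCC", strrep("CGA", 10))
    near <- plantCds(cds, contigLen = 400L, cdsStart0 = 50L)
    expect_error(extractArms(near$genome, near$cds, 2L, armLength = 200L),
                 "contig boundary")
    # under first_valid the codon scan also skips infeasible flanks
    expect_error(selectInsertionCodon(near$genome, near$cds,
                                      armLength = 300L),
                 "no valid insertion codon")

    # two-exon CDS: codon 2 sits right before the junction, arms would span it
    set.seed(3)
    bases <- paste(sample(c("A", "C", "G"), 3000, replace = TRUE),
                   collapse = "")
    genome <- Biostrings::DNAStringSet(bases); names(genome) <- "chr1"
    ex1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1012), "+")
    ex2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1501, 1788), "+")
    cdsGr <- c(ex1, ex2)
    expect_error(extractArms(genome, cdsGr, 2L, armLength = 200L),
                 "splice junction")
})

test_that("GFF3-driven design works end to end and validity rules hold", {
    dir <- withr::local_tempdir()
    cds <- paste0("ATG", "GCA", strrep("CAG", 140))
    fx <- plantCds(cds, contigLen = 2000L, cdsStart0 = 900L, seed = 8)
    fa <- file.path(dir, "genome.fasta")
    Biostrings::writeXStringSet(fx$genome, fa)
    gff <- file.path(dir, "ann.gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\ttest\tgene\t901\t1323\t.\t+\t.\tID=geneA",
        "chr1\ttest\tmRNA\t901\t1323\t.\t+\t.\tID=txA;Parent=geneA",
        "chr1\ttest\tCDS\t901\t1323\t.\t+\t0\tID=cdsA;Parent=txA"), gff)
    designs <- designArms(fa, gff, transcripts = "txA")
    d <- designs[["txA"]]
    expect_s4_class(d, "ArmDesign")
    expect_identical(d@geneId, "geneA")
    expect_identical(d@codonIndex, 2L)
    expect_identical(length(leftArm(d)), 200L)
    expect_identical(length(rightArm(d)), 200L)
    expect_false(endsWith(as.character(leftArm(d)), "T"))

    paths <- writeArmDesigns(designs, tsvPath = file.path(dir, "arms.tsv"),
                             fastaPath = file.path(dir, "arms.fasta"))
    tab <- read.delim(paths[1])
    expect_identical(tab$left_arm, as.character(leftArm(d)))
    expect_identical(tab$arm_length, 200L)
    seqs <- Biostrings::readDNAStringSet(paths[2])
    expect_identical(as.character(seqs[["txA_left_arm"]]),
                     as.character(leftArm(d)))

    expect_error(designArms(fa, gff, transcripts = "nope"), "no CDS")
})
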