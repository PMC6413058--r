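# Genome/annotation reading, intergenic classification, array parsing.

makeGenbank <- function(seq, feats, circular = FALSE, id = "TEST01") {
    lines <- c(sprintf("LOCUS       %s             %d bp    DNA     %s   BCT",
                       id, nchar(seq), if (circular) "circular" else "linear"),
               "DEFINITION  synthetic test record.",
               "FEATURES             Location/Qualifiers")
    for (f in feats) {
        loc <- sprintf("%d..%d", f$start, f$end)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        lines <- c(lines,
                   sprintf("     gene            %s", loc),
                   sprintf("                     /gene=\"%s\"", f$id))
    }
    lines <- c(lines, "ORIGIN")
    for (o in seq(1, nchar(seq), by = 60))
        lines <- c(lines, sprintf("%9d %s", o,
                                  substr(seq, o, min(nchar(seq), o + 59))))
    c(lines, "//")
}

test_that("GenBank fixtures read back identically", {
    set.seed(101)
    seq <- randomDna(1000)
    gb <- makeGenbank(seq, list(list(start = 101, end = 400, strand = "+",
                                     id = "gA")))
    path <- withr::local_tempfile(fileext = ".gb")
    writeLines(gb, path)
    r <- readGenome(path, format = "genbank")
    expect_s4_class(r$genome, "ScanGenome")
    expect_equal(genomeLength(r$genome), 1000L)
    expect_equal(as.character(genomeSeq(r$genome)), seq)
    expect_false(isCircular(r$genome))
    expect_equal(length(r$features), 1L)
    expect_equal(IRanges::start(r$features), 101L)
    expect_equal(IRanges::end(r$features), 400L)
    expect_equal(S4Vectors::mcols(r$features)$gene_id, "gA")

    # complement() location and circular topology
    gb2 <- makeGenbank(seq, list(list(start = 11, end = 100, strand = "-",
                                      id = "gB")), circular = TRUE)
    writeLines(gb2, path)
    r2 <- readGenome(path, format = "genbank")
    expect_true(isCircular(r2$genome))
    expect_equal(as.character(GenomicRanges::strand(r2$features)), "-")
    expect_equal(IRanges::start(r2$features), 11L)
    expect_equal(IRanges::end(r2$features), 100L)
})

test_that("FASTA + GFF3 round-trips through the simulator's emitters", {
    sim <- simulateHost(genomeLength = 15000L, seed = 5L)
    dir <- withr::local_tempdir()
    paths <- writeSimulated(sim, dir)
    r <- readGenome(paths["genome"], format = "fasta", gff = paths["gff"])
    expect_equal(as.character(genomeSeq(r$genome)),
                 as.character(genomeSeq(sim$genome)))
    expect_equal(IRanges::start(r$features), IRanges::start(sim$features))
    expect_equal(IRanges::end(r$features), IRanges::end(sim$features))
    expect_equal(as.character(GenomicRanges::strand(r$features)),
                 as.character(GenomicRanges::strand(sim$features)))
    arr <- readArrayFasta(paths["array"])
    expect_equal(as.character(spacerSeqs(arr)),
                 as.character(spacerSeqs(sim$array)))
    located <- locateArray(arr, r$genome)
    expect_equal(arrayRange(located), arrayRange(sim$array))
    expect_equal(spacerRanges(located), spacerRanges(sim$array))
})

test_that("overlapping gene features merge to an interval union", {
    gr <- GenomicRanges::GRanges("g", IRanges::IRanges(
        c(10, 50, 200), c(80, 120, 300)), strand = c("+", "-", "+"))
    S4Vectors::mcols(gr)$gene_id <- c("a", "b", "c")
    tiles <- codingTiling(gr)
    # independent interval-union oracle by per-base marking
    covered <- rep(FALSE, 400)
    for (i in 1:3) covered[IRanges::start(gr)[i]:IRanges::end(gr)[i]] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    expect_equal(IRanges::start(tiles), starts[runs$values])
    expect_equal(IRanges::end(tiles), ends[runs$values])
})

test_that("intergenic gaps are categorized by flanking gene orientation", {
    mk <- function(strands) {
        gr <- GenomicRanges::GRanges("g", IRanges::IRanges(
            c(101, 501), c(300, 700)), strand = strands)
        S4Vectors::mcols(gr)$gene_id <- c("L", "R")
        classifyIntergenic(gr, 1000L)
    }
    midCat <- function(ig) S4Vectors::mcols(ig)$category[
        IRanges::start(ig) == 301]
    expect_equal(midCat(mk(c("-", "+"))), "divergent")
    expect_equal(midCat(mk(c("+", "-"))), "convergent")
    expect_equal(midCat(mk(c("+", "+"))), "upstream")
    expect_equal(midCat(mk(c("-", "-"))), "upstream")
    # linear terminal gaps: single flanking gene
    ig <- mk(c("+", "-"))
    expect_equal(S4Vectors::mcols(ig)$category[IRanges::start(ig) == 1],
                 "upstream")   # right gene +, points away from the end
    expect_equal(S4Vectors::mcols(ig)$category[IRanges::start(ig) == 701],
                 "upstream")   # left gene -, points away from the end
    expect_true(is.na(S4Vectors::mcols(ig)$left_gene_id[
        IRanges::start(ig) == 1]))
    expect_error(classifyIntergenic(GenomicRanges::GRanges(), 1000L,
                                    circular = FALSE), "no gene features")
})

test_that("coding tiles and intergenic regions tile a linear genome", {
    sim <- simulateHost(genomeLength = 20000L, seed = 9L)
    tiles <- codingTiling(sim$features)
    starts <- c(IRanges::start(tiles), IRanges::start(sim$intergenic))
    ends <- c(IRanges::end(tiles), IRanges::end(sim$intergenic))
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    expect_equal(starts[1L], 1L)
    expect_equal(ends[length(ends)], 20000L)
    expect_true(all(starts[-1L] == ends[-length(ends)] + 1L))
})

test_that("intergenic categories are invariant under genome reverse
           complement", {
    sim <- simulateHost(genomeLength = 20000L, seed = 13L)
    L <- genomeLength(sim$genome)
    rc_feats <- GenomicRanges::GRanges("g", IRanges::IRanges(
        L - IRanges::end(sim$features) + 1L,
        L - IRanges::start(sim$features) + 1L),
        strand = chartr("+-", "-+",
                        as.character(GenomicRanges::strand(sim$features))))
    S4Vectors::mcols(rc_feats)$gene_id <-
        S4Vectors::mcols(sim$features)$gene_id
    rc_ig <- classifyIntergenic(sort(rc_feats, ignore.strand = TRUE), L)
    fwd <- S4Vectors::mcols(sim$intergenic)$category
    # region at [s,e] maps to [L-e+1, L-s+1]
    key <- paste(L - IRanges::end(sim$intergenic) + 1L,
                 L - IRanges::start(sim$intergenic) + 1L)
    rc_key <- paste(IRanges::start(rc_ig), IRanges::end(rc_ig))
    rc_cat <- S4Vectors::mcols(rc_ig)$category[match(key, rc_key)]
    # a gene pointing away from a gap still points away after reverse
    # complement, so every category maps to itself
    interior <- !is.na(S4Vectors::mcols(sim$intergenic)$left_gene_id) &
        !is.na(S4Vectors::mcols(sim$intergenic)$right_gene_id)
    expect_equal(rc_cat[interior], fwd[interior])
})

test_that("CRISPR loci split into ordered spacers between repeat copies", {
    set.seed(77)
    rep28 <- randomDna(28)
    s1 <- randomDna(32); s2 <- randomDna(33)
    locus <- paste0(rep28, s1, rep28, s2, rep28)
    arr <- parseCrisprArray(locus, rep28)
    expect_equal(length(spacerSeqs(arr)), 2L)
    expect_equal(as.character(spacerSeqs(arr)[[1L]]), s1)
    expect_equal(as.character(spacerSeqs(arr)[[2L]]), s2)
    # leader on the right reverses the numbering
    arrR <- parseCrisprArray(locus, rep28, leaderSide = "right")
    expect_equal(as.character(spacerSeqs(arrR)[[1L]]), s2)
    # 13 repeat copies -> 12 spacers
    sp12 <- replicate(12, randomDna(32))
    locus12 <- paste0(rep28, paste0(sp12, rep28, collapse = ""))
    arr12 <- parseCrisprArray(locus12, rep28)
    expect_equal(length(spacerSeqs(arr12)), 12L)
    expect_equal(unname(as.character(spacerSeqs(arr12))), unname(sp12))
    # re-concatenation reproduces the locus
    rebuilt <- paste0(rep28, paste0(as.character(spacerSeqs(arr12)), rep28,
                                    collapse = ""))
    expect_equal(rebuilt, locus12)
    # a single repeat copy cannot be an array
    expect_error(parseCrisprArray(paste0(randomDna(50), rep28,
                                         randomDna(50)), rep28),
                 "fewer than 2 repeat copies")
})

test_that("near-exact repeat copies are recognized, zero-length spacers
           skipped", {
    set.seed(78)
    rep28 <- randomDna(28)
    mut <- rep28
    substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 5, 5))[1L]
    s1 <- randomDna(32)
    arr <- parseCrisprArray(paste0(rep28, s1, mut), rep28)
    expect_equal(as.character(spacerSeqs(arr)[[1L]]), s1)
    expect_warning(
        parseCrisprArray(paste0(rep28, s1, rep28, rep28), rep28),
        "zero-length")
})
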