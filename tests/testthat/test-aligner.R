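# Local alignment, declumping, hit reporting, self-hit exclusion.

test_that("optimal local alignment scores are structurally forced", {
    set.seed(21)
    sp <- randomDna(32)
    h <- smithWaterman(sp, sp)
    expect_equal(h$score, 160L)                 # 32 x match(+5)
    expect_equal(c(h$s_start, h$s_end, h$q_start, h$q_end),
                 c(1L, 32L, 1L, 32L))
    planted <- paste0(strrep("T", 20), "ACGT", strrep("T", 20))
    h2 <- smithWaterman("ACGT", planted)
    expect_equal(h2$score, 20L)
    expect_equal(h2$s_start, 21L)
    expect_error(smithWaterman("", "ACGT"), "non-empty")
})

test_that("k-best scores and intervals match the independent DP oracle", {
    set.seed(22)
    for (rep_ in 1:40) {
        q <- randomDna(sample(8:40, 1))
        s <- randomDna(sample(60:400, 1))
        k <- sample(1:4, 1)
        got <- smithWaterman(q, s, k = k)
        exp_ <- oracleSw(q, s, k = k)
        expect_equal(got$score, exp_$score)
        expect_equal(got$s_start, exp_$s_start)
        expect_equal(got$s_end, exp_$s_end)
    }
})

test_that("declumped hits are non-overlapping with non-increasing scores", {
    set.seed(23)
    g <- randomDna(5000)
    sp <- randomDna(32)
    h <- topKHits(sp, g, "direct", k = 10)
    expect_true(all(diff(h$score) <= 0))
    o <- order(h$g_start)
    expect_true(all(h$g_start[o][-1L] > h$g_end[o][-nrow(h)]))
})

test_that("two identical planted protospacers tie at ranks 1 and 2", {
    set.seed(24)
    sp <- randomDna(32)
    g <- paste0(randomDna(300), sp, randomDna(300), sp, randomDna(300))
    h <- topKHits(sp, g, "direct", k = 5)
    expect_equal(h$score[1:2], c(160L, 160L))
    expect_equal(sort(h$g_start[1:2]), c(301L, 633L))
    # k = 1 equals the single optimal alignment
    h1 <- topKHits(sp, g, "direct", k = 1)
    sw <- smithWaterman(sp, g)
    expect_equal(h1$score, sw$score)
    expect_equal(h1$g_start, sw$s_start)
})

test_that("strand symmetry: reverse-strand hits equal direct-strand hits
           of the reverse-complemented spacer", {
    set.seed(25)
    g <- randomDna(3000)
    sp <- randomDna(32)
    rev_hits <- topKHits(sp, g, "reverse", k = 8)
    dir_rc <- topKHits(revCompChr(sp), g, "direct", k = 8)
    expect_equal(rev_hits$score, dir_rc$score)
    expect_equal(sort(rev_hits$g_start), sort(dir_rc$g_start))
    expect_equal(sort(rev_hits$g_end), sort(dir_rc$g_end))
})

test_that("merging ranks by score with direct-first, leftmost tie-breaks", {
    d <- data.frame(strand = "direct", g_start = c(100L, 10L),
                    g_end = c(130L, 40L), score = c(40L, 40L),
                    q_start = 1L, q_end = 31L)
    r <- data.frame(strand = "reverse", g_start = 500L, g_end = 530L,
                    score = c(45L), q_start = 1L, q_end = 31L)
    m <- mergeAndRank(d, r)
    expect_equal(m$rank, 1:3)
    expect_equal(m$score, c(45L, 40L, 40L))
    expect_equal(m$strand[1L], "reverse")
    expect_equal(m$g_start[2:3], c(10L, 100L))  # leftmost tie first
    rr <- data.frame(strand = "reverse", g_start = 10L, g_end = 40L,
                     score = 40L, q_start = 1L, q_end = 31L)
    m2 <- mergeAndRank(d[1L, ], rr)
    expect_equal(m2$strand, c("direct", "reverse"))  # direct wins the tie
})

test_that("the CRISPR-locus self-hit ranks first on the reverse strand
           and exclusion retains 2k-1 targets per spacer", {
    sim <- simulateHost(genomeLength = 20000L, seed = 7L)
    h <- scanSpacers(sim$array, sim$genome, k = 10L)
    sr <- spacerRanges(sim$array)
    for (i in seq_along(sr)) {
        sid <- names(spacerSeqs(sim$array))[i]
        top <- h[h$spacer_id == sid & h$rank == 1L, ]
        expect_equal(top$strand, "reverse")
        expect_equal(top$score, 160L)
        expect_equal(top$g_start, IRanges::start(sr)[i])
        expect_equal(top$g_end, IRanges::end(sr)[i])
    }
    he <- excludeSelfHits(h, sim$array)
    expect_equal(as.vector(table(he$spacer_id)), rep(19L, 12L))
    expect_true(all(tapply(he$rank, he$spacer_id,
                           function(r) identical(sort(r), 1:19))))
    # phage genomes carry no array: the list passes through unchanged
    ph <- simulatePhages(1, genomeLength = 5000L, seed = 3L)[[1L]]
    hp <- scanSpacers(sim$array, ph, k = 3L)
    hp2 <- excludeSelfHits(hp, sim$array, host = FALSE)
    expect_equal(nrow(hp2), nrow(hp))
    # a hit table with no array overlap on a host genome warns
    fake <- data.frame(spacer_id = "S1", g_start = 1L, g_end = 30L,
                       rank = 1L)
    expect_warning(excludeSelfHits(fake, sim$array), "self-hit")
})

test_that("theoretical start extends the actual start upstream by the
           unaligned spacer prefix", {
    h <- data.frame(strand = c("direct", "direct", "reverse"),
                    g_start = c(100L, 100L, 100L),
                    g_end = c(130L, 127L, 127L),
                    q_start = c(1L, 4L, 4L))
    ts <- theoreticalStart(h, 1000L)
    expect_equal(ts$theoretical_start, c(100L, 97L, 130L))
    expect_false(any(ts$edge_truncated))
    edge <- theoreticalStart(data.frame(strand = "direct", g_start = 2L,
                                        g_end = 30L, q_start = 4L), 1000L)
    expect_true(edge$edge_truncated)
})

test_that("theoretical starts mirror under reverse complementation of a
           planted fixture", {
    set.seed(26)
    sp <- randomDna(32)
    # plant a copy whose first 3 spacer bases are corrupted, forcing a
    # trimmed alignment with q_start = 4
    proto <- sp
    substr(proto, 1, 3) <- c("GGG")
    if (substr(sp, 1, 3) == "GGG") substr(proto, 1, 3) <- "CCC"
    g <- paste0(randomDna(200), proto, randomDna(200))
    h <- topKHits(sp, g, "direct", k = 1)
    h$strand <- "direct"
    ts <- theoreticalStart(h, nchar(g))$theoretical_start
    expect_equal(ts, 201L)  # the planted protospacer's first coordinate
    grc <- revCompChr(g)
    h2 <- topKHits(sp, grc, "reverse", k = 1)
    h2$strand <- "reverse"
    ts2 <- theoreticalStart(h2, nchar(grc))$theoretical_start
    expect_equal(ts2, nchar(g) - 201L + 1L)  # mirrored coordinate
})

test_that("subject masking excludes alignments from masked intervals", {
    set.seed(27)
    sp <- randomDna(32)
    g <- paste0(randomDna(100), sp, randomDna(100))
    h <- smithWaterman(sp, g, k = 1)
    expect_equal(h$s_start, 101L)
    hm <- smithWaterman(sp, g, k = 1,
                        mask = IRanges::IRanges(101L, 132L))
    expect_true(nrow(hm) == 0L || hm$s_start > 132L || hm$s_end < 101L)
    expect_true(all(hm$score < 160L))
})
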