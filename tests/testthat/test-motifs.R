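# PAM-position motif extraction, counting, and overrepresentation calls.

test_that("planted PAM triplets are recovered from both strands", {
    sim <- simulateHost(genomeLength = 30000L, nPlants = 24L,
                        mismatchRange = 0L, pam = "AAG", seed = 41L)
    he <- excludeSelfHits(scanSpacers(sim$array, sim$genome), sim$array)
    for (r in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[r, ]
        hit <- he[he$spacer_id == tr$spacer_id & he$g_start == tr$start &
                  he$g_end == tr$end, ]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$strand, tr$strand)
        ctx <- extractContext(hit, sim$genome, "adjacent3")
        expect_equal(ctx, "AAG")
        # the upstream6 window nests the adjacent triplet as its
        # start-proximal suffix
        u6 <- extractContext(hit, sim$genome, "upstream6")
        expect_equal(substr(u6, 4, 6), ctx)
        # full-length alignment: empty gap segment
        expect_equal(extractContext(hit, sim$genome, "gap_segment"), "")
    }
    expect_true(any(sim$truth$strand == "direct") &&
                any(sim$truth$strand == "reverse"))
})

test_that("context orientation switch reverse-complements the window", {
    sim <- simulateHost(genomeLength = 20000L, nPlants = 6L,
                        mismatchRange = 0L, pam = "ATG", seed = 42L)
    he <- excludeSelfHits(scanSpacers(sim$array, sim$genome), sim$array)
    tr <- sim$truth[1L, ]
    hit <- he[he$spacer_id == tr$spacer_id & he$g_start == tr$start, ]
    a3 <- extractContext(hit, sim$genome, "adjacent3")
    a5 <- extractContext(hit, sim$genome, "adjacent3",
                         orientation = "5to3")
    expect_equal(a3, "ATG")
    expect_equal(a5, revCompChr(a3))
})

test_that("motif tables count one window per adjacent triplet and all
           overlapping windows in longer contexts", {
    tab <- countMotifs(c("AAG", "AAG", "TTC"))
    expect_equal(length(tab), 64L)
    expect_equal(unname(tab["AAG"]), 2L)
    expect_equal(unname(tab["TTC"]), 1L)
    expect_equal(sum(tab), 3L)
    expect_equal(attr(tab, "n_hits"), 3L)

    t6 <- countMotifs("AAGAAG")
    expect_equal(sum(t6), 4L)    # 6 - 3 + 1 overlapping windows
    expect_equal(unname(t6["AAG"]), 2L)
    expect_equal(unname(t6["AGA"]), 1L)
    expect_equal(unname(t6["GAA"]), 1L)
    t6n <- countMotifs("AAGAAG", overlapping = FALSE)
    expect_equal(sum(t6n), 2L)
    # windows containing ambiguity codes are skipped
    tn <- countMotifs(c("ANG", NA, "", "AAG"))
    expect_equal(sum(tn), 1L)
    expect_equal(attr(tn, "n_hits"), 1L)
})

test_that("adjacent3 counts sum to the number of non-skipped hits", {
    sim <- simulateHost(genomeLength = 15000L, seed = 43L)
    he <- excludeSelfHits(scanSpacers(sim$array, sim$genome), sim$array)
    ctx <- extractContext(he, sim$genome, "adjacent3")
    tab <- countMotifs(ctx)
    expect_equal(sum(tab), sum(!is.na(ctx)))
    expect_equal(length(tab), 64L)
})

test_that("motif context tables are invariant under genome reverse
           complementation", {
    sim <- simulateHost(genomeLength = 12000L, seed = 44L)
    L <- genomeLength(sim$genome)
    he <- excludeSelfHits(scanSpacers(sim$array, sim$genome), sim$array)
    tab <- countMotifs(extractContext(he, sim$genome, "adjacent3"))
    rc_genome <- ScanGenome("rc",
        revCompChr(as.character(genomeSeq(sim$genome))),
        provenance = "host")
    rc_array <- CrisprArray(
        spacerSeqs(sim$array), repeatSeq(sim$array),
        arrayStart = L - IRanges::end(arrayRange(sim$array)) + 1L,
        arrayEnd = L - IRanges::start(arrayRange(sim$array)) + 1L,
        spacerRanges = IRanges::IRanges(
            L - IRanges::end(spacerRanges(sim$array)) + 1L,
            L - IRanges::start(spacerRanges(sim$array)) + 1L),
        arrayStrand = "+")
    he2 <- excludeSelfHits(scanSpacers(rc_array, rc_genome), rc_array)
    tab2 <- countMotifs(extractContext(he2, rc_genome, "adjacent3"))
    expect_equal(as.integer(tab2), as.integer(tab))
})

test_that("Poisson calls flag planted enrichment and stay silent on
           identical backgrounds", {
    base <- setNames(rep(3L, 64L), names(countMotifs(character(0))))
    reps <- replicate(5, base, simplify = FALSE)
    calls <- motifCalls(base, reps)
    expect_true(all(calls$status == "ns"))
    # observed 30 against lambda 5 is far outside the central 99.7% band
    real <- base; real["AAG"] <- 30L
    reps5 <- replicate(5, { x <- base; x["AAG"] <- 5L; x },
                       simplify = FALSE)
    calls2 <- motifCalls(real, reps5)
    expect_equal(calls2$status[calls2$motif == "AAG"], "over")
    expect_equal(calls2$upper[calls2$motif == "AAG"],
                 qpois(1 - (1 - 0.9973) / 2, 5))
    expect_lt(qpois(1 - (1 - 0.9973) / 2, 5), 30)
    # a zero-lambda zero-observation motif is ns by convention
    expect_true(all(calls2$status[calls2$lambda == 0 &
                                  calls2$observed == 0] == "ns"))
    expect_error(motifCalls(base, reps[1]), "at least 2")
})

test_that("reference-PAM overlap percentages follow set arithmetic", {
    calls <- data.frame(motif = c("AAG", "ATG", "CCC"),
                        status = c("over", "over", "ns"))
    expect_equal(pamOverlap(calls, c("AAG")), 50)
    expect_equal(pamOverlap(calls, c("AAG", "ATG", "TTT")), 100)
    expect_equal(pamOverlap(calls, c("GGG")), 0)
    expect_true(is.na(pamOverlap(data.frame(motif = "AAG",
                                            status = "ns"), "AAG")))
    expect_error(pamOverlap(calls, character(0)), "empty reference")
})

test_that("PAM wheel normalizes abundances and reports both score
           conventions", {
    real <- setNames(rep(0L, 64L), names(countMotifs(character(0))))
    real["AAG"] <- 30L; real["ATG"] <- 10L
    calls <- data.frame(motif = names(real),
                        status = ifelse(names(real) %in% c("AAG", "ATG"),
                                        "over", "ns"))
    w <- pamWheel(real, calls)
    expect_equal(w$rel_abundance, c(0.75, 0.25))
    expect_equal(sum(w$rel_abundance), 1)
    expect_equal(w$score_fraction, w$rel_abundance)
    # the literal printed formula is negative for every motif
    expect_true(all(w$score_literal < 0))
    expect_equal(w$score_literal, c(-0.25, -0.75))
    one <- pamWheel(real, transform(calls,
        status = ifelse(motif == "AAG", "over", "ns")))
    expect_equal(one$rel_abundance, 1)
    expect_error(pamWheel(real, transform(calls, status = "ns")),
                 "no overrepresented")
})

test_that("reference PAM lists parse with declared orientation", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# orientation: 3to5", "AAG", "atg", "", "TTC"), path)
    ref <- readPamReference(path)
    expect_equal(as.character(ref), c("AAG", "ATG", "TTC"))
    expect_equal(attr(ref, "orientation"), "3to5")
})
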