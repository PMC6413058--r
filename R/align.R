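#' @useDynLib spacerscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Alignment scoring scheme
#'
#' The nucleotide scoring used for every local alignment in the package:
#' the ACGT diagonal/off-diagonal values of the NUC44 substitution matrix
#' (+5 match, -4 mismatch) and a linear gap model in which every gapped
#' position costs `gap`. IUPAC ambiguity codes score as mismatches
#' against everything, including themselves.
#'
#' @param match match score (> 0), default 5.
#' @param mismatch mismatch score (< 0), default -4.
#' @param gap positive per-gapped-position penalty, default 8.
#'
#' @return A named list of class `scoringScheme`.
#' @export
scoringScheme <- function(match = 5L, mismatch = -4L, gap = 8L) {
    match <- as.integer(match); mismatch <- as.integer(mismatch)
    gap <- as.integer(gap)
    stopifnot(match > 0L, mismatch < 0L, gap > 0L)
    structure(list(match = match, mismatch = mismatch, gap = gap),
              class = "scoringScheme")
}

# DNA character -> integer codes: A,C,G,T -> 0..3, everything else -> -1
.encodeDna <- local({
    lut <- rep(-1L, 256L)
    lut[utf8ToInt("A") + 1L] <- 0L
    lut[utf8ToInt("C") + 1L] <- 1L
    lut[utf8ToInt("G") + 1L] <- 2L
    lut[utf8ToInt("T") + 1L] <- 3L
    function(x) lut[as.integer(charToRaw(x)) + 1L]
})

.revComp <- function(x) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                       "")[[1L]]), collapse = "")
}

# core k-best wrapper on character sequences; mask is an IRanges (subject
# coordinates) whose positions no alignment may consume
.swKBest <- function(query, subject, scoring = scoringScheme(), k = 1L,
                     minScore = 1L, mask = NULL) {
    if (!nchar(query) || !nchar(subject))
        stop("query and subject must be non-empty sequences")
    ms <- if (is.null(mask)) integer(0) else as.integer(start(mask))
    me <- if (is.null(mask)) integer(0) else as.integer(end(mask))
    m <- sw_kbest_c(.encodeDna(query), .encodeDna(subject),
                    scoring$match, scoring$mismatch, scoring$gap,
                    as.integer(k), as.integer(minScore), ms, me)
    m
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Exhaustive dynamic-programming local alignment of two nucleotide
#' sequences under [scoringScheme()]. Traceback ties are broken
#' deterministically (diagonal over up over left; among equal-score cells
#' the earliest subject end wins), so results are reproducible.
#'
#' @param query,subject nucleotide strings (character or `DNAString`).
#' @param scoring a [scoringScheme()].
#' @param k return up to `k` best non-overlapping alignments
#'   (Waterman-Eggert declumping: each reported subject interval is
#'   masked before the next pass). Default 1.
#' @param minScore report alignments with score >= `minScore` only.
#' @param mask optional `IRanges` of subject positions no alignment may
#'   use.
#'
#' @return A data.frame with columns `score`, `s_start`, `s_end`,
#'   `q_start`, `q_end` (1-based inclusive), ordered by decreasing score;
#'   zero rows when no alignment reaches `minScore`.
#' @examples
#' smithWaterman("ACGT", "TTTTACGTTTTT")  # score 20 at the planted offset
#' @export
smithWaterman <- function(query, subject, scoring = scoringScheme(),
                          k = 1L, minScore = 1L, mask = NULL) {
    m <- .swKBest(toupper(as.character(query)),
                  toupper(as.character(subject)), scoring, k, minScore, mask)
    as.data.frame(m)
}

#' k best non-overlapping hits of a spacer on one genome strand
#'
#' Repeated optimal local alignment with previously reported subject
#' intervals masked (declumping). Reverse-strand hits are computed
#' against the reverse complement of the genome and mapped back to
#' direct-strand coordinates.
#'
#' @param spacer spacer sequence (character or `DNAString`).
#' @param genome a [ScanGenome-class] (or plain sequence).
#' @param strand `"direct"` or `"reverse"`.
#' @param k maximum number of hits (default 10).
#' @param scoring a [scoringScheme()].
#' @param mask optional `IRanges` of direct-strand genome positions to
#'   exclude from the search (e.g. the CRISPR array interval).
#'
#' @return A data.frame of hits: `strand`, `g_start`, `g_end` (1-based,
#'   direct strand), `score`, `q_start`, `q_end` (spacer orientation),
#'   descending score. Fewer than `k` rows when fewer positive-score
#'   alignments exist.
#' @export
topKHits <- function(spacer, genome, strand = c("direct", "reverse"),
                     k = 10L, scoring = scoringScheme(), mask = NULL) {
    strand <- match.arg(strand)
    subject <- if (is(genome, "ScanGenome")) as.character(genomeSeq(genome))
               else toupper(as.character(genome))
    L <- nchar(subject)
    if (strand == "reverse") {
        subject <- .revComp(subject)
        if (!is.null(mask))
            mask <- IRanges(L - end(mask) + 1L, L - start(mask) + 1L)
    }
    m <- .swKBest(toupper(as.character(spacer)), subject, scoring,
                  k = k, minScore = 1L, mask = mask)
    if (!nrow(m)) {
        return(data.frame(strand = character(0), g_start = integer(0),
                          g_end = integer(0), score = integer(0),
                          q_start = integer(0), q_end = integer(0)))
    }
    g_start <- m[, "s_start"]; g_end <- m[, "s_end"]
    if (strand == "reverse") {
        tmp <- L - g_end + 1L
        g_end <- L - g_start + 1L
        g_start <- tmp
    }
    data.frame(strand = strand, g_start = g_start, g_end = g_end,
               score = m[, "score"], q_start = m[, "q_start"],
               q_end = m[, "q_end"])
}

#' Merge direct- and reverse-strand hit lists and assign ranks
#'
#' Hits from both strands of one (spacer, genome) pair are pooled and
#' ordered by descending alignment score; ties are broken by strand
#' (direct first) and then by lower genome start. Ranks 1..m are
#' assigned. A logical `self` column, when present, wins any score tie
#' (the CRISPR-locus self-alignment is reported first among equals).
#'
#' @param direct,reverse data.frames from [topKHits()].
#' @return The merged data.frame with a `rank` column.
#' @export
mergeAndRank <- function(direct, reverse) {
    hits <- rbind(direct, reverse)
    if (!nrow(hits)) {
        hits$rank <- integer(0)
        return(hits)
    }
    selfFlag <- if ("self" %in% names(hits)) !hits$self else rep(FALSE, nrow(hits))
    o <- order(-hits$score, selfFlag, hits$strand != "direct", hits$g_start)
    hits <- hits[o, , drop = FALSE]
    hits$rank <- seq_len(nrow(hits))
    rownames(hits) <- NULL
    hits
}

#' Remove trivial CRISPR-locus self-hits
#'
#' Every hit whose genome interval overlaps the CRISPR array interval is
#' removed (the spacer's own locus, and any alignment to repeats or
#' neighbouring spacers, is a trivial hit, not a target) and the
#' remaining hits are re-ranked per spacer. On a host genome the removed
#' set is expected to contain the rank-1 hit (the spacer self-alignment);
#' a warning is raised otherwise.
#'
#' @param hits a ranked hit data.frame (needs `g_start`, `g_end`, `rank`,
#'   and `spacer_id` when several spacers are present).
#' @param array a [CrisprArray-class].
#' @param host logical: whether `hits` come from a real host genome (the
#'   rank-1 self-hit warning only applies there).
#'
#' @return The filtered, re-ranked data.frame.
#' @export
excludeSelfHits <- function(hits, array, host = TRUE) {
    if (!nrow(hits)) return(hits)
    a1 <- array@arrayStart; a2 <- array@arrayEnd
    drop <- hits$g_end >= a1 & hits$g_start <= a2
    if (host && (!any(drop) || !any(hits$rank[drop] == 1L)))
        warning("no rank-1 self-hit found at the CRISPR locus of a host ",
                "genome; self-alignments are expected to rank first")
    out <- hits[!drop, , drop = FALSE]
    if (!nrow(out)) { out$rank <- integer(0); return(out) }
    if ("spacer_id" %in% names(out)) {
        out <- out[order(out$spacer_id, out$rank), , drop = FALSE]
        out$rank <- unlist(lapply(split(seq_len(nrow(out)), out$spacer_id),
                                  seq_along), use.names = FALSE)
        out <- out[order(out$spacer_id, out$rank), , drop = FALSE]
    } else {
        out <- out[order(out$rank), , drop = FALSE]
        out$rank <- seq_len(nrow(out))
    }
    rownames(out) <- NULL
    out
}

#' Theoretical alignment start
#'
#' The actual alignment start extended upstream by the length of the
#' unaligned spacer prefix (the spacer bases before the first aligned
#' one), anchoring the PAM windows. Upstream means decreasing
#' direct-strand coordinate for a direct-strand hit and increasing
#' coordinate for a reverse-strand hit.
#'
#' @param hits hit data.frame with `strand`, `g_start`, `g_end`,
#'   `q_start`.
#' @param genomeLength genome length; starts falling outside
#'   `[1, genomeLength]` are flagged `edge_truncated` (such hits are
#'   excluded from PAM analysis).
#'
#' @return `hits` with `theoretical_start` and `edge_truncated` columns.
#' @export
theoreticalStart <- function(hits, genomeLength) {
    if (!nrow(hits)) {
        hits$theoretical_start <- integer(0)
        hits$edge_truncated <- logical(0)
        return(hits)
    }
    off <- hits$q_start - 1L
    ts <- ifelse(hits$strand == "direct", hits$g_start - off,
                 hits$g_end + off)
    hits$theoretical_start <- as.integer(ts)
    hits$edge_truncated <- ts < 1L | ts > genomeLength
    hits
}

#' Scan all spacers of an array against one genome
#'
#' Runs the full per-genome hit-reporting scheme: for every spacer, the
#' `k` best non-overlapping local alignments per strand are computed,
#' merged and ranked; theoretical starts are annotated.
#'
#' On genomes of host provenance the CRISPR array interval is masked
#' during the search, so that alignments to the array locus (repeats,
#' neighbouring spacers) never occupy target slots. On the real host
#' (`provenance == "host"`) the spacer's self-alignment against the
#' unmasked array locus is additionally computed and inserted as the
#' rank-1 hit of its strand (that strand then carries the self-hit plus
#' the `k - 1` best targets), reproducing the reporting scheme in which
#' the self-hit always ranks first and, once excluded with
#' [excludeSelfHits()], each spacer retains `2k - 1` targets.
#'
#' @param array a [CrisprArray-class].
#' @param genome a [ScanGenome-class].
#' @param k hits per strand (default 10).
#' @param scoring a [scoringScheme()].
#' @param maskArray logical: mask the array interval (default: genome is
#'   of host provenance).
#' @param reportSelf logical: compute and prepend the self-hit (default:
#'   `provenance(genome) == "host"`).
#'
#' @return A data.frame of ranked hits with columns `spacer_id`,
#'   `genome_id`, `provenance`, `strand`, `g_start`, `g_end`, `score`,
#'   `q_start`, `q_end`, `theoretical_start`, `edge_truncated`, `rank`.
#' @seealso [excludeSelfHits()], [classifyHits()], [categoryProfile()].
#' @export
scanSpacers <- function(array, genome, k = 10L, scoring = scoringScheme(),
                        maskArray = NULL, reportSelf = NULL) {
    stopifnot(is(array, "CrisprArray"), is(genome, "ScanGenome"), k >= 1L)
    prov <- provenance(genome)
    if (is.null(maskArray))
        maskArray <- prov %in% c("host", "randomized-host")
    if (is.null(reportSelf))
        reportSelf <- identical(prov, "host")
    mask <- if (maskArray) arrayRange(array) else NULL
    L <- genomeLength(genome)
    gseq <- as.character(genomeSeq(genome))
    spacers <- spacerSeqs(array)

    res <- lapply(names(spacers), function(sid) {
        sp <- as.character(spacers[[sid]])
        self <- NULL
        kd <- k; kr <- k
        if (reportSelf) {
            self <- .selfHit(sp, gseq, array, scoring)
            if (!is.null(self)) {
                if (self$strand == "direct") kd <- k - 1L else kr <- k - 1L
            }
        }
        dh <- if (kd >= 1L) topKHits(sp, gseq, "direct", kd, scoring, mask)
              else topKHits(sp, gseq, "direct", 1L, scoring, mask)[0L, ]
        rh <- if (kr >= 1L) topKHits(sp, gseq, "reverse", kr, scoring, mask)
              else topKHits(sp, gseq, "reverse", 1L, scoring, mask)[0L, ]
        dh$self <- rep(FALSE, nrow(dh)); rh$self <- rep(FALSE, nrow(rh))
        if (!is.null(self)) {
            self$self <- TRUE
            if (self$strand == "direct") dh <- rbind(self, dh)
            else rh <- rbind(self, rh)
        }
        hits <- mergeAndRank(dh, rh)
        if (nrow(hits)) hits$spacer_id <- sid
        hits
    })
    hits <- do.call(rbind, res)
    if (is.null(hits) || !nrow(hits)) {
        hits <- data.frame(spacer_id = character(0), strand = character(0),
                           g_start = integer(0), g_end = integer(0),
                           score = integer(0), q_start = integer(0),
                           q_end = integer(0), rank = integer(0))
    }
    hits$genome_id <- genomeId(genome)
    hits$provenance <- prov
    hits <- theoreticalStart(hits, L)
    cols <- c("spacer_id", "genome_id", "provenance", "strand", "g_start",
              "g_end", "score", "q_start", "q_end", "theoretical_start",
              "edge_truncated", "rank")
    hits[, cols]
}

# best alignment of one spacer against the (unmasked) array locus, on
# either strand; returns a one-row topKHits-shaped data.frame or NULL
.selfHit <- function(spacer, gseq, array, scoring) {
    a1 <- array@arrayStart; a2 <- array@arrayEnd
    locus <- substring(gseq, a1, a2)
    best <- NULL
    for (strand in c("direct", "reverse")) {
        h <- topKHits(spacer, locus, strand, k = 1L, scoring = scoring)
        if (nrow(h) && (is.null(best) || h$score[1L] > best$score[1L]))
            best <- h[1L, , drop = FALSE]
    }
    if (is.null(best)) return(NULL)
    best$g_start <- best$g_start + a1 - 1L
    best$g_end <- best$g_end + a1 - 1L
    best
}
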