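#' @importFrom stats qpois t.test
NULL

.ALL_TRIPLETS <- local({
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1]
    sort(apply(g, 1L, paste, collapse = ""))
})

.complementStr <- function(x) chartr("ACGT", "TGCA", x)

#' Extract a PAM flanking context for each hit
#'
#' The three contexts are anchored at the theoretical alignment start
#' (the first spacer nucleotide position):
#'
#' * `adjacent3`: the 3 nt immediately upstream (5' side on the targeted
#'   strand) of the theoretical start - the canonical interference-PAM
#'   position.
#' * `upstream6`: the 6 nt immediately upstream; its 3 nt suffix closest
#'   to the start equals `adjacent3`.
#' * `gap_segment`: the bases between the theoretical and the actual
#'   alignment start (length = unaligned spacer prefix; empty when the
#'   alignment starts at spacer base 1).
#'
#' All contexts are read on the targeted strand (the reverse complement
#' of the strand carrying the hit) and reported 3'->5' by default, with
#' `orientation = "5to3"` as the alternative convention.
#'
#' @param hits hit data.frame with `theoretical_start`, `strand`,
#'   `g_start`, `g_end`, `q_start`.
#' @param genome a [ScanGenome-class] (or plain sequence string).
#' @param context `"adjacent3"`, `"upstream6"` or `"gap_segment"`.
#' @param orientation `"3to5"` (default) or `"5to3"`.
#'
#' @return A character vector, one element per hit; `NA` for hits whose
#'   window extends past a linear genome end (context skipped) or which
#'   are edge-truncated.
#' @export
extractContext <- function(hits, genome,
                           context = c("adjacent3", "upstream6",
                                       "gap_segment"),
                           orientation = c("3to5", "5to3")) {
    context <- match.arg(context)
    orientation <- match.arg(orientation)
    gseq <- if (is(genome, "ScanGenome")) as.character(genomeSeq(genome))
            else toupper(as.character(genome))
    L <- nchar(gseq)
    n <- nrow(hits)
    out <- rep(NA_character_, n)
    if (!n) return(out)
    wlen <- switch(context, adjacent3 = 3L, upstream6 = 6L,
                   gap_segment = hits$q_start - 1L)
    if (length(wlen) == 1L) wlen <- rep(wlen, n)
    for (i in seq_len(n)) {
        if (isTRUE(hits$edge_truncated[i])) next
        ts <- hits$theoretical_start[i]
        w <- wlen[i]
        if (w == 0L) { out[i] <- ""; next }
        if (hits$strand[i] == "direct") {
            lo <- ts - w; hi <- ts - 1L
            if (lo < 1L) next  # window past genome start: context skipped
            frame <- substring(gseq, lo, hi)  # 5'->3' in protospacer frame
        } else {
            lo <- ts + 1L; hi <- ts + w
            if (hi > L) next
            frame <- .revComp(substring(gseq, lo, hi))
        }
        out[i] <- if (orientation == "3to5") .complementStr(frame)
                  else .revComp(.complementStr(frame))
    }
    out
}

#' Count 3 nt motifs in a set of flanking contexts
#'
#' For `adjacent3` contexts each (3 nt) string contributes one count; for
#' the longer `upstream6` and `gap_segment` contexts every overlapping
#' 3-mer window is counted (switch to non-overlapping windows with
#' `overlapping = FALSE`). Windows containing non-ACGT characters are
#' skipped. The count table always has exactly 64 keys.
#'
#' @param contexts character vector from [extractContext()] (`NA` and
#'   empty elements are skipped).
#' @param overlapping slide the 3-mer window by 1 (default) or by 3.
#'
#' @return A named integer vector over all 64 triplets, with attribute
#'   `n_hits` = number of contexts contributing at least one window.
#' @export
countMotifs <- function(contexts, overlapping = TRUE) {
    counts <- setNames(integer(64L), .ALL_TRIPLETS)
    contributed <- 0L
    step <- if (overlapping) 1L else 3L
    for (ctx in contexts) {
        if (is.na(ctx) || nchar(ctx) < 3L) next
        starts <- seq(1L, nchar(ctx) - 2L, by = step)
        kmers <- substring(ctx, starts, starts + 2L)
        kmers <- kmers[!grepl("[^ACGT]", kmers)]
        if (!length(kmers)) next
        contributed <- contributed + 1L
        tab <- table(kmers)
        counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    attr(counts, "n_hits") <- contributed
    counts
}

#' Call over/underrepresented motifs against a randomized background
#'
#' For each of the 64 triplets, a Poisson distribution is fitted to the
#' motif's counts over the randomized replicates (lambda = mean replicate
#' count) and central quantile bounds at the configured level (default
#' 99.73%, the two-sided 3 sigma equivalent) are derived. A motif is
#' `over` when its real count exceeds the upper bound, `under` when below
#' the lower bound, `ns` otherwise (a motif absent everywhere is `ns` by
#' convention). The p-value is a paired comparison of the real count
#' against the replicate counts, which for a single real count reduces
#' to - and is implemented as - a one-sample t-test of the
#' replicate-minus-real differences.
#'
#' @param real named count vector from [countMotifs()] on the real
#'   genome.
#' @param replicates list of count vectors from the randomized replicates
#'   (>= 2).
#' @param level central Poisson coverage for the bounds (default
#'   0.9973).
#'
#' @return A data.frame: `motif`, `observed`, `lambda`, `lower`,
#'   `upper`, `status`, `p_value`.
#' @export
motifCalls <- function(real, replicates, level = 0.9973) {
    if (length(replicates) < 2L)
        stop("motif calls need at least 2 background replicates")
    m <- vapply(replicates, function(r) r[.ALL_TRIPLETS], numeric(64L))
    lambda <- rowMeans(m)
    alpha <- (1 - level) / 2
    lower <- qpois(alpha, lambda)
    upper <- qpois(1 - alpha, lambda)
    obs <- as.numeric(real[.ALL_TRIPLETS])
    status <- ifelse(obs > upper, "over",
                     ifelse(obs < lower, "under", "ns"))
    status[lambda == 0 & obs == 0] <- "ns"
    pv <- vapply(seq_len(64L), function(i) {
        d <- m[i, ] - obs[i]
        if (sd(d) == 0) return(if (all(d == 0)) 1 else NA_real_)
        t.test(d)$p.value
    }, numeric(1))
    data.frame(motif = .ALL_TRIPLETS, observed = obs, lambda = lambda,
               lower = lower, upper = upper, status = status, p_value = pv)
}

#' Overlap between overrepresented motifs and reference interference PAMs
#'
#' @param calls a [motifCalls()] table.
#' @param reference character vector of experimentally confirmed
#'   interference-PAM triplets (supplied by the user, e.g. via
#'   [readPamReference()]; the package bundles none).
#'
#' @return Percentage (0-100) of overrepresented motifs present in the
#'   reference set; `NA` when no motif is overrepresented.
#' @export
pamOverlap <- function(calls, reference) {
    if (!length(reference))
        stop("empty reference PAM set")
    reference <- toupper(reference)
    over <- calls$motif[calls$status == "over"]
    if (!length(over)) return(NA_real_)
    100 * length(intersect(over, reference)) / length(over)
}

#' Read a reference PAM list
#'
#' Plain-text format: one triplet per line; lines starting with `#` are
#' header/comment lines (the first may declare the orientation, e.g.
#' `# orientation: 3to5`, recorded as an attribute).
#'
#' @param path file path.
#' @return Character vector of triplets with attribute `orientation`
#'   (default `"3to5"` when undeclared).
#' @export
readPamReference <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^#", lines, value = TRUE)
    ori <- "3to5"
    m <- regmatches(hdr, regexec("orientation:\\s*(\\S+)", hdr))
    m <- Filter(function(x) length(x) == 2L, m)
    if (length(m)) ori <- m[[1L]][2L]
    pams <- toupper(trimws(grep("^#", lines, value = TRUE, invert = TRUE)))
    pams <- pams[nzchar(pams)]
    structure(pams, orientation = ori)
}

#' PAM-wheel table of overrepresented motifs
#'
#' Relative abundance of every overrepresented motif (its real count over
#' the summed counts of all overrepresented motifs), plus two versions of
#' the wheel's bracketed score: `score_literal`, the formula as printed
#' ((count - total) / total, which is negative for every motif), and
#' `score_fraction`, the count fraction it presumably intends. Neither
#' is silently corrected into the other.
#'
#' @param real named count vector on the real genome.
#' @param calls a [motifCalls()] table.
#' @param reference optional reference PAM set; adds an `in_reference`
#'   flag.
#'
#' @return A data.frame: `motif`, `count`, `rel_abundance`,
#'   `score_literal`, `score_fraction` (+ `in_reference`); abundances sum
#'   to 1. Errors when no motif is overrepresented.
#' @export
pamWheel <- function(real, calls, reference = NULL) {
    over <- calls$motif[calls$status == "over"]
    if (!length(over))
        stop("no overrepresented motifs: PAM wheel undefined")
    cnt <- as.numeric(real[over])
    total <- sum(cnt)
    out <- data.frame(motif = over, count = cnt,
                      rel_abundance = cnt / total,
                      score_literal = (cnt - total) / total,
                      score_fraction = cnt / total)
    if (!is.null(reference))
        out$in_reference <- out$motif %in% toupper(reference)
    out
}
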