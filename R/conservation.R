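#' @importFrom utils read.delim
NULL

.BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read 12-column tabular homology-search output
#'
#' Standard `blastn -outfmt 6` column order. The search itself is run out
#' of process; this module only post-processes its output.
#'
#' @param path path to the tabular file (TSV, no header; `#` comment
#'   lines tolerated).
#' @return A data.frame with the standard column names.
#' @export
readBlastTab <- function(path) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 12L)
        stop("expected 12 tabular columns (outfmt 6), got ", ncol(df))
    df <- df[, 1:12]
    names(df) <- .BLAST6_COLS
    df
}

#' Filter search records by E-value
#'
#' Strict inequality: a record with `evalue` exactly equal to `eMax` is
#' dropped. Records whose E-value does not parse as a finite
#' non-negative number are rejected with a warning.
#'
#' @param records data.frame with an `evalue` column.
#' @param eMax E-value bound (default `1e-3`).
#' @return The filtered data.frame. Idempotent.
#' @export
filterRecords <- function(records, eMax = 1e-3) {
    ev <- suppressWarnings(as.numeric(records$evalue))
    bad <- !is.finite(ev) | ev < 0
    if (any(bad))
        warning(sum(bad), " record(s) with malformed E-value rejected")
    records[!bad & ev < eMax, , drop = FALSE]
}

#' Classify a search hit as CRISPR-array context by repeat flanks
#'
#' A subject hit is classified as lying inside a CRISPR array when it is
#' surrounded by repeats: the `flankLen` bases on each side of the
#' subject interval are locally aligned against the repeat sequence and
#' both flank scores must reach `cutoff` (25 by default - the natural
#' cutoff below which random-flank alignment scores fall off steeply).
#' Flanks truncated by the contig end are used as available and flagged.
#'
#' @param record one row of a [readBlastTab()] table.
#' @param subjects a named [Biostrings::DNAStringSet] of subject contigs
#'   (the local FASTA the search ran against).
#' @param repeatSeq the CRISPR repeat.
#' @param flankLen flank length (default 40).
#' @param cutoff minimum local alignment score per flank (default 25).
#' @param scoring a [scoringScheme()].
#'
#' @return A list: `upstream_score`, `downstream_score`, `in_array`,
#'   `truncated`, `resolved` (`FALSE` with all else `NA` when the
#'   subject id cannot be found; such calls are excluded from tallies).
#' @export
arrayContext <- function(record, subjects, repeatSeq, flankLen = 40L,
                         cutoff = 25L, scoring = scoringScheme()) {
    sid <- as.character(record$sseqid)
    if (!sid %in% names(subjects))
        return(list(upstream_score = NA_integer_,
                    downstream_score = NA_integer_, in_array = NA,
                    truncated = NA, resolved = FALSE))
    subj <- as.character(subjects[[sid]])
    lo <- min(record$sstart, record$send)
    hi <- max(record$sstart, record$send)
    upA <- max(1L, lo - flankLen); upB <- lo - 1L
    dnA <- hi + 1L; dnB <- min(nchar(subj), hi + flankLen)
    truncated <- (upB - upA + 1L) < flankLen || (dnB - dnA + 1L) < flankLen
    flankScore <- function(a, b) {
        if (b < a) return(0L)
        f <- substring(subj, a, b)
        max(0L,
            smithWaterman(repeatSeq, f, scoring)$score[1L],
            smithWaterman(repeatSeq, .revComp(f), scoring)$score[1L],
            na.rm = TRUE)
    }
    up <- flankScore(upA, upB)
    dn <- flankScore(dnA, dnB)
    list(upstream_score = up, downstream_score = dn,
         in_array = up >= cutoff && dn >= cutoff,
         truncated = truncated, resolved = TRUE)
}

#' Tally filtered records by taxon group
#'
#' Groups retained search records by a user-supplied subject-to-taxon map
#' (2-column TSV: subject id, taxon); no taxonomy database is bundled.
#'
#' @param records filtered records.
#' @param taxonMap data.frame or 2-column TSV path mapping `sseqid` to a
#'   taxon label.
#' @return A table of record counts per taxon (`"unmapped"` collects
#'   subjects absent from the map).
#' @export
tallyByTaxon <- function(records, taxonMap) {
    if (is.character(taxonMap))
        taxonMap <- read.delim(taxonMap, header = FALSE,
                               col.names = c("sseqid", "taxon"),
                               stringsAsFactors = FALSE)
    tax <- taxonMap$taxon[match(records$sseqid, taxonMap$sseqid)]
    tax[is.na(tax)] <- "unmapped"
    table(tax)
}

#' Compare spacer and target phylogenetic hit distributions
#'
#' The spacer side is summarized by the total hit count over all spacers
#' with a Poisson 3 sigma interval (`total +/- 3 * sqrt(total)`); the
#' target side by the mean, over targets, of the per-target hit totals,
#' with the analogous interval. The verdict is whether the two intervals
#' are disjoint (a 3 sigma separation).
#'
#' @param spacerCounts integer vector of per-spacer hit counts.
#' @param targetCounts matrix of hit counts, spacers x targets (or a
#'   vector of per-target totals).
#' @param sigma interval half-width in sigma units (default 3).
#'
#' @return A list: `spacer_total`, `spacer_interval`, `target_mean`,
#'   `target_interval`, `separated`.
#' @export
distributionCompare <- function(spacerCounts, targetCounts, sigma = 3) {
    if (!length(spacerCounts) || !length(targetCounts))
        stop("empty count input")
    sTot <- sum(spacerCounts)
    tTot <- if (is.matrix(targetCounts)) colSums(targetCounts)
            else as.numeric(targetCounts)
    tMean <- mean(tTot)
    sInt <- c(sTot - sigma * sqrt(sTot), sTot + sigma * sqrt(sTot))
    tInt <- c(tMean - sigma * sqrt(tMean), tMean + sigma * sqrt(tMean))
    list(spacer_total = sTot, spacer_interval = sInt,
         target_mean = tMean, target_interval = tInt,
         separated = sInt[2L] < tInt[1L] || tInt[2L] < sInt[1L])
}

#' Score distribution of random flanks against a repeat
#'
#' Empirical distribution of local alignment scores of random `flankLen`
#' nt sequences against a repeat, used to inspect the flank score cutoff
#' (the distribution falls off steeply below the cutoff).
#'
#' @param repeatSeq the repeat.
#' @param n number of random flanks.
#' @param flankLen flank length (default 40).
#' @param scoring a [scoringScheme()].
#' @param seed RNG seed.
#' @return Integer vector of `n` scores.
#' @export
flankScoreDistribution <- function(repeatSeq, n = 500L, flankLen = 40L,
                                   scoring = scoringScheme(), seed = 1L) {
    .withSeed(seed, {
        vapply(seq_len(n), function(i) {
            f <- paste(sample(c("A", "C", "G", "T"), flankLen,
                              replace = TRUE), collapse = "")
            as.integer(smithWaterman(repeatSeq, f, scoring)$score[1L])
        }, integer(1))
    })
}
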