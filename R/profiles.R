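#' @importFrom stats sd t.test ks.test qpois setNames
NULL

#' Select hits belonging to one functional category
#'
#' Maps a category name to a logical row filter on a classified hit
#' table. Categories: `"all"`, `"coding"`, `"intergenic"`, `"RNA+"`,
#' `"RNA-"`, `"divergent"`, `"convergent"`, `"upstream"`, `"DC"`, `"RC"`.
#'
#' @param hits classified hit data.frame (see [classifyHits()]).
#' @param category category name.
#' @return A logical vector over rows of `hits`.
#' @export
categorySelector <- function(hits, category) {
    switch(category,
        "all" = rep(TRUE, nrow(hits)),
        "coding" = hits$region_type == "coding",
        "intergenic" = hits$region_type == "intergenic",
        "RNA+" = !is.na(hits$rna_category) & hits$rna_category == "RNA+",
        "RNA-" = !is.na(hits$rna_category) & hits$rna_category == "RNA-",
        "divergent" = ,
        "convergent" = ,
        "upstream" = !is.na(hits$intergenic_category) &
                     hits$intergenic_category == category,
        "DC" = hits$genome_strand == "DC",
        "RC" = hits$genome_strand == "RC",
        stop("unknown category: ", category))
}

#' Spacer alignment count (SAC) for one threshold
#'
#' The SAC value for threshold `k` is the number of hits with rank at
#' most `k`, summed over all spacers of the array, restricted to hits
#' satisfying `select`. The SAC value for threshold 3, for instance, is
#' computed from the first 3 ranked alignments of every spacer.
#'
#' @param hits ranked hit data.frame (`spacer_id`, `rank`).
#' @param k rank threshold (>= 1).
#' @param select logical row filter (default: all hits).
#' @return Integer SAC value.
#' @export
sacValue <- function(hits, k, select = NULL) {
    if (is.null(select)) select <- rep(TRUE, nrow(hits))
    sum(hits$rank <= k & select, na.rm = TRUE)
}

#' Spacer alignment score (SAS) for one threshold
#'
#' The mean alignment score of the hits counted by [sacValue()]; `NA`
#' (absent) when no hit qualifies - never 0.
#'
#' @inheritParams sacValue
#' @return Numeric SAS value, or `NA` when the selection is empty.
#' @export
sasValue <- function(hits, k, select = NULL) {
    if (is.null(select)) select <- rep(TRUE, nrow(hits))
    s <- hits$score[hits$rank <= k & select]
    if (!length(s)) NA_real_ else mean(s)
}

#' SAC/SAS threshold profile for one category
#'
#' @param hits classified, ranked hit data.frame.
#' @param category category name (see [categorySelector()]) or a logical
#'   row filter.
#' @param thresholds integer rank thresholds (default `1:19`, the host
#'   grid after self-hit exclusion; use `1:20` for phage genomes).
#'
#' @return A data.frame `category`, `threshold`, `sac`, `sas`.
#' @export
categoryProfile <- function(hits, category = "all", thresholds = 1:19) {
    if (is.character(category)) {
        select <- categorySelector(hits, category)
        label <- category
    } else {
        select <- category
        label <- "custom"
    }
    data.frame(category = label, threshold = as.integer(thresholds),
               sac = vapply(thresholds, function(k)
                   sacValue(hits, k, select), numeric(1)),
               sas = vapply(thresholds, function(k)
                   sasValue(hits, k, select), numeric(1)))
}

#' Randomized-background confidence bounds for a SAC profile
#'
#' Fits a normal distribution per threshold to the SAC values of the
#' randomized replicates (sample mean and n-1 standard deviation) and
#' derives confidence bounds at a configurable multiple of the standard
#' deviation (default 3 sigma).
#'
#' @param profiles list of per-replicate profiles from
#'   [categoryProfile()], all on the same threshold grid.
#' @param sigma bound half-width in standard deviations (default 3).
#' @param value which profile column to summarize (`"sac"` or `"sas"`).
#'
#' @return A data.frame `threshold`, `bg_mean`, `bg_sd`, `lower`,
#'   `upper`.
#' @export
backgroundBounds <- function(profiles, sigma = 3, value = "sac") {
    if (length(profiles) < 2L)
        stop("background bounds need at least 2 replicates ",
             "(sd is undefined for n < 2)")
    thr <- profiles[[1L]]$threshold
    for (p in profiles)
        if (!identical(p$threshold, thr))
            stop("replicate profiles are on different threshold grids")
    m <- vapply(profiles, function(p) p[[value]], numeric(length(thr)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    data.frame(threshold = thr, bg_mean = mu, bg_sd = s,
               lower = mu - sigma * s, upper = mu + sigma * s)
}

#' Significance of a real profile against its randomized background
#'
#' Per-threshold z-scores `(sac_real - bg_mean) / bg_sd` (undefined where
#' the background sd is 0) and an overall paired t-test of the real SAC
#' values against the background means across the threshold grid (the
#' profile is the paired object; the per-threshold z is always reported
#' alongside).
#'
#' @param real a [categoryProfile()] for the real genome.
#' @param background a [backgroundBounds()] on the same grid.
#' @param value profile column (default `"sac"`).
#'
#' @return A list: `z` (data.frame `threshold`, `z`), `p` (overall paired
#'   t-test p-value; `NA` with fewer than 2 thresholds or a degenerate
#'   pairing).
#' @export
profileSignificance <- function(real, background, value = "sac") {
    if (!identical(as.integer(real$threshold),
                   as.integer(background$threshold)))
        stop("real and background profiles are on different grids")
    z <- (real[[value]] - background$bg_mean) / background$bg_sd
    z[background$bg_sd == 0] <- NA_real_
    p <- NA_real_
    if (nrow(real) >= 2L) {
        d <- real[[value]] - background$bg_mean
        if (sd(d) > 0)
            p <- t.test(real[[value]], background$bg_mean,
                        paired = TRUE)$p.value
        else p <- if (all(d == 0)) 1 else 0
    }
    list(z = data.frame(threshold = real$threshold, z = z), p = p)
}

#' Compare two alignment-score distributions
#'
#' Two-sided independent two-sample t-test and two-sample
#' Kolmogorov-Smirnov test between two pools of alignment scores (e.g.
#' all retained hits on the real genome vs on its randomizations), plus
#' normalized histograms of both pools on a common grid.
#'
#' @param poolA,poolB numeric score vectors (>= 2 each).
#' @param breaks histogram break count passed to [hist()].
#'
#' @return A list: `t_p`, `ks_p`, `ks_stat`, `hist_a`, `hist_b`
#'   (histogram objects with `density` normalized). `t_p` is `NA` when
#'   both pools are degenerate (zero variance); the KS test is always
#'   computed.
#' @export
scoreDistributionTests <- function(poolA, poolB, breaks = 30) {
    stopifnot(length(poolA) >= 2L, length(poolB) >= 2L)
    t_p <- if (sd(poolA) == 0 && sd(poolB) == 0) NA_real_
           else t.test(poolA, poolB)$p.value
    ks <- suppressWarnings(ks.test(poolA, poolB))
    rng <- range(c(poolA, poolB))
    brk <- seq(rng[1L] - 0.5, rng[2L] + 0.5, length.out = breaks + 1L)
    list(t_p = t_p, ks_p = ks$p.value, ks_stat = unname(ks$statistic),
         hist_a = graphics::hist(poolA, breaks = brk, plot = FALSE),
         hist_b = graphics::hist(poolB, breaks = brk, plot = FALSE))
}
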