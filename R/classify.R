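#' @importFrom IRanges IRanges findOverlaps pintersect overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Classify hits by genomic context
#'
#' Assigns every hit the functional categories used by the SAC/SAS
#' profiles:
#'
#' * `region_type`: `"coding"` or `"intergenic"`, by majority of the
#'   hit's aligned genome positions (exact ties go to coding); the
#'   container is the merged coding tile or intergenic region holding
#'   that majority.
#' * `rna_category` (coding hits only): a hit on the gene's coding strand
#'   means the actual crRNA target is the template strand, so
#'   interference can act only on DNA (`"RNA-"`); a hit on the template
#'   strand puts the target on the coding strand, where both DNA and
#'   mRNA are targetable (`"RNA+"`). The gene strand is taken from the
#'   individual gene with the largest overlap with the hit.
#' * `intergenic_category` (intergenic hits only): `"divergent"`,
#'   `"convergent"` or `"upstream"` from [classifyIntergenic()].
#' * `genome_strand`: `"DC"` (direct chain) or `"RC"` (reverse chain).
#' * `boundary_spanning`: `TRUE` when the hit is not fully contained in
#'   its container, so both containment conventions can be compared.
#'
#' Classification uses the hit's aligned genome interval, not the
#' theoretical start.
#'
#' @param hits hit data.frame from [scanSpacers()] (after
#'   [excludeSelfHits()] for host genomes).
#' @param features `GRanges` of gene features (unmerged, stranded).
#' @param genomeLength genome length.
#' @param circular circular topology flag.
#' @param intergenic optional precomputed [classifyIntergenic()] result.
#'
#' @return `hits` with columns `region_type`, `rna_category`,
#'   `intergenic_category`, `genome_strand`, `container_id`,
#'   `boundary_spanning` appended.
#' @export
classifyHits <- function(hits, features, genomeLength, circular = FALSE,
                         intergenic = NULL) {
    n <- nrow(hits)
    hits$genome_strand <- ifelse(hits$strand == "direct", "DC", "RC")
    hits$region_type <- rep(NA_character_, n)
    hits$rna_category <- rep(NA_character_, n)
    hits$intergenic_category <- rep(NA_character_, n)
    hits$container_id <- rep(NA_character_, n)
    hits$boundary_spanning <- rep(NA, n)
    if (!n) return(hits)
    if (is.null(intergenic))
        intergenic <- classifyIntergenic(features, genomeLength, circular)
    coding <- codingTiling(features)
    hr <- IRanges(hits$g_start, hits$g_end)
    cr <- IRanges(start(coding), end(coding))
    ir <- IRanges(start(intergenic), end(intergenic))
    fr <- IRanges(start(features), end(features))
    fstrand <- as.character(GenomicRanges::strand(features))
    fids <- S4Vectors::mcols(features)$gene_id
    icat <- S4Vectors::mcols(intergenic)$category
    iids <- paste0("IGR_", start(intergenic), "_", end(intergenic))

    ovWidth <- function(query, subject) {
        # per-query total overlap width with each overlapping subject
        fo <- findOverlaps(query, subject)
        w <- width(pintersect(query[queryHits(fo)], subject[subjectHits(fo)]))
        list(q = queryHits(fo), s = subjectHits(fo), w = w)
    }
    oc <- ovWidth(hr, cr)
    oi <- ovWidth(hr, ir)
    og <- ovWidth(hr, fr)

    codingW <- integer(n)
    if (length(oc$q)) {
        agg <- tapply(oc$w, oc$q, sum)
        codingW[as.integer(names(agg))] <- as.integer(agg)
    }
    hw <- width(hr)
    isCoding <- codingW * 2L >= hw  # majority; exact tie -> coding
    hits$region_type <- ifelse(isCoding, "coding", "intergenic")

    pickBest <- function(ov, i) {
        # subject with the largest overlap for hit i (first wins ties)
        sel <- ov$q == i
        if (!any(sel)) return(NA_integer_)
        ov$s[sel][which.max(ov$w[sel])]
    }
    for (i in seq_len(n)) {
        if (isCoding[i]) {
            gi <- pickBest(og, i)
            if (!is.na(gi)) {
                hits$container_id[i] <- fids[gi]
                onCodingStrand <-
                    (fstrand[gi] == "+" & hits$strand[i] == "direct") |
                    (fstrand[gi] == "-" & hits$strand[i] == "reverse")
                hits$rna_category[i] <- if (onCodingStrand) "RNA-" else "RNA+"
                ci <- pickBest(oc, i)
                hits$boundary_spanning[i] <-
                    !(hits$g_start[i] >= start(cr)[ci] &
                      hits$g_end[i] <= end(cr)[ci])
            }
        } else {
            ri <- pickBest(oi, i)
            if (!is.na(ri)) {
                hits$container_id[i] <- iids[ri]
                hits$intergenic_category[i] <- icat[ri]
                hits$boundary_spanning[i] <-
                    !(hits$g_start[i] >= start(ir)[ri] &
                      hits$g_end[i] <= end(ir)[ri])
            }
        }
    }
    hits
}
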