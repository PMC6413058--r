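#' @importFrom IRanges IRanges start end gaps
NULL

# run expr with a given RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a reproducible per-replicate seed
#'
#' Mixes a base seed with a replicate index so that any single replicate
#' of a randomized background can be regenerated in isolation. The result
#' stays below 2^31.
#'
#' @param seed base integer seed.
#' @param i replicate index (>= 1).
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, i) {
    s <- (as.double(seed) %% 2147483647) * 69069 + as.double(i) * 104729
    as.integer(s %% 2147483647)
}

# the full per-region tiling used by the shuffler: merged coding
# intervals plus the gaps between them, covering [1, L]
.regionTiling <- function(features, genomeLength) {
    if (is.null(features) || !length(features))
        return(IRanges(1L, as.integer(genomeLength)))
    coding <- IRanges::reduce(IRanges(start(features), end(features)))
    inter <- gaps(coding, start = 1L, end = as.integer(genomeLength))
    tiling <- c(coding, inter)
    tiling[order(start(tiling))]
}

#' Composition-preserving genome randomization
#'
#' Produces a null genome in which, within every coding region and every
#' intergenic region independently, the output is a uniform random
#' permutation of that region's nucleotides. Per-region nucleotide
#' content (GC, composition) is therefore conserved exactly, while all
#' sequence order is destroyed. The annotation is carried over unchanged.
#' Genomes without annotation (e.g. phages) are shuffled as a single
#' whole-genome region.
#'
#' @param genome a [ScanGenome-class].
#' @param features `GRanges` of gene features, or `NULL` for a
#'   whole-genome shuffle.
#' @param seed integer seed; the same (genome, features, seed) triple
#'   always yields the same output.
#'
#' @return A [ScanGenome-class] with provenance `"randomized-host"` or
#'   `"randomized-phage"`.
#' @export
randomizeGenome <- function(genome, features = NULL, seed = 1L) {
    stopifnot(is(genome, "ScanGenome"))
    tiling <- .regionTiling(features, genomeLength(genome))
    chars <- strsplit(as.character(genomeSeq(genome)), "")[[1L]]
    .withSeed(seed, {
        for (i in seq_along(tiling)) {
            idx <- start(tiling)[i]:end(tiling)[i]
            if (length(idx) > 1L)
                chars[idx] <- chars[sample(idx)]
        }
    })
    prov <- if (provenance(genome) %in% c("host", "randomized-host"))
        "randomized-host" else "randomized-phage"
    ScanGenome(paste0(genomeId(genome), "|rand|", seed),
               paste(chars, collapse = ""),
               circular = isCircular(genome), provenance = prov)
}

#' Generate a randomized-genome background
#'
#' `n` independent composition-preserving randomizations of a genome,
#' with per-replicate seeds derived from `(seed, replicate index)` so any
#' single replicate is reproducible in isolation.
#'
#' @inheritParams randomizeGenome
#' @param n number of randomizations (default 30, the replicate count
#'   used for all background statistics).
#'
#' @return A list of `n` [ScanGenome-class] objects.
#' @export
makeBackground <- function(genome, features = NULL, n = 30L, seed = 1L) {
    stopifnot(n >= 1L)
    lapply(seq_len(n), function(i)
        randomizeGenome(genome, features, deriveSeed(seed, i)))
}

#' Write genomes as FASTA with provenance-encoding headers
#'
#' @param genomes a list of [ScanGenome-class] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenomesFasta <- function(genomes, path) {
    seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g)
        as.character(genomeSeq(g)), character(1)))
    names(seqs) <- vapply(genomes, function(g)
        paste0(genomeId(g), "|", provenance(g)), character(1))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
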