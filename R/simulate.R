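#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.sampleDna <- function(n, composition) {
    paste(sample(names(composition), n, replace = TRUE,
                 prob = composition), collapse = "")
}

# sample one element (length-1 x is returned as-is, never treated as 1:x)
.sample1 <- function(x, prob = NULL) {
    if (length(x) == 1L) x else sample(x, 1L, prob = prob)
}

#' Simulate an annotated host genome with an embedded CRISPR array
#'
#' Generates the full ground-truth test bed for the pipeline: a genome of
#' the requested length tiled by genes in mixed orientations (creating
#' divergent, convergent and upstream intergenic regions), a CRISPR
#' array (alternating repeats and spacers, leader-proximal spacer first)
#' embedded in a dedicated intergenic gap, and optionally planted
#' protospacers - mutated copies of the spacers placed with configurable
#' strand bias, region-category weights, mismatch counts and planted PAM
#' triplets. Every planted protospacer is recorded in a truth table and
#' placed wholly within a single region of its sampled category, so the
#' planted categories are crisp.
#'
#' @param genomeLength genome length in nt (default 100000).
#' @param nSpacers number of spacers (default 12).
#' @param spacerLength spacer length in nt (default 32, a typical Type
#'   I-E dimension).
#' @param repeatLength repeat length in nt (default 28).
#' @param geneLengthRange,gapLengthRange uniform sampling ranges for gene
#'   and intergenic gap lengths (defaults 300-1500 and 60-260 nt, giving
#'   a bacterial-like ~85% coding density).
#' @param composition named base probabilities (default uniform).
#' @param arrayStrand genome strand carrying the array (default `"-"`,
#'   so spacer self-alignments fall on the reverse strand).
#' @param nPlants number of planted protospacers (default 0).
#' @param rho probability that a plant goes on the reverse strand
#'   (strand bias; default 0.5 = unbiased).
#' @param plantStrands optional explicit per-plant strand vector
#'   (`"direct"`/`"reverse"`, length `nPlants`), overriding `rho` - the
#'   per-protospacer analogue of the plant table's strand column.
#' @param regionWeights named non-negative weights over `coding`,
#'   `divergent`, `convergent`, `upstream` for the planted region
#'   category (default: proportional to total region length).
#' @param mismatchRange integer vector of mismatch counts sampled per
#'   plant (default `0:2`); mismatches are placed at interior spacer
#'   positions so the planted locus stays the optimal full-length
#'   alignment.
#' @param pam optional PAM triplet written immediately upstream of each
#'   planted protospacer on the targeted strand (in the 3'->5'
#'   convention of [extractContext()]).
#' @param pamFraction fraction of plants receiving the PAM (default 1).
#' @param circular circular topology flag for the emitted genome
#'   (default `FALSE`).
#' @param seed RNG seed; same seed, same output.
#'
#' @return A list: `genome` ([ScanGenome-class]), `features` (`GRanges`
#'   of genes), `array` ([CrisprArray-class]), `intergenic`
#'   ([classifyIntergenic()] map), `truth` (data.frame of plants:
#'   `plant_id`, `spacer_id`, `strand`, `start`, `end`, `category`,
#'   `n_mismatches`, `mismatch_positions`, `pam`).
#' @seealso [simulatePhages()], [writeSimulated()], [scanSpacers()].
#' @export
simulateHost <- function(genomeLength = 100000L, nSpacers = 12L,
                         spacerLength = 32L, repeatLength = 28L,
                         geneLengthRange = c(300L, 1500L),
                         gapLengthRange = c(60L, 260L),
                         composition = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                         arrayStrand = "-", nPlants = 0L, rho = 0.5,
                         plantStrands = NULL, regionWeights = NULL,
                         mismatchRange = 0:2, pam = NULL, pamFraction = 1,
                         circular = FALSE, seed = 1L) {
    stopifnot(rho >= 0, rho <= 1, nSpacers >= 1L,
              all(mismatchRange < spacerLength / 2),
              is.null(plantStrands) ||
                  (length(plantStrands) == nPlants &&
                   all(plantStrands %in% c("direct", "reverse"))))
    .withSeed(seed, .simulateHostImpl(
        genomeLength, nSpacers, spacerLength, repeatLength,
        geneLengthRange, gapLengthRange, composition, arrayStrand,
        nPlants, rho, plantStrands, regionWeights, mismatchRange, pam,
        pamFraction, circular))
}

.simulateHostImpl <- function(genomeLength, nSpacers, spacerLength,
                              repeatLength, geneLengthRange, gapLengthRange,
                              composition, arrayStrand, nPlants, rho,
                              plantStrands, regionWeights, mismatchRange,
                              pam, pamFraction, circular) {
    L <- as.integer(genomeLength)
    bases <- c("A", "C", "G", "T")

    # CRISPR array: repeat, S1, repeat, S2, ..., Sn, repeat
    rep_seq <- .sampleDna(repeatLength, composition)
    spacers <- vapply(seq_len(nSpacers), function(i)
        .sampleDna(spacerLength, composition), character(1))
    names(spacers) <- paste0("S", seq_len(nSpacers))
    locus <- rep_seq
    sp_locus_start <- integer(nSpacers)
    for (i in seq_len(nSpacers)) {
        sp_locus_start[i] <- nchar(locus) + 1L
        locus <- paste0(locus, spacers[i], rep_seq)
    }
    arrayLen <- nchar(locus)
    margin <- 40L
    if (L < arrayLen + 2L * margin + sum(geneLengthRange))
        stop("genome too short to hold the CRISPR array and genes")

    # alternating gap/gene layout; one mid-genome gap widened to hold
    # the array
    gene_start <- integer(0); gene_end <- integer(0)
    gene_strand <- character(0)
    array_start <- NA_integer_
    pos <- 1L
    arrayPlaced <- FALSE
    repeat {
        gapLen <- .sample1(gapLengthRange[1L]:gapLengthRange[2L])
        if (!arrayPlaced && pos > 0.4 * L) {
            gapLen <- arrayLen + 2L * margin
            array_start <- pos + margin
            arrayPlaced <- TRUE
        }
        pos <- pos + gapLen
        geneLen <- .sample1(geneLengthRange[1L]:geneLengthRange[2L])
        if (pos + geneLen > L - gapLengthRange[1L]) break
        gene_start <- c(gene_start, pos)
        gene_end <- c(gene_end, pos + geneLen - 1L)
        gene_strand <- c(gene_strand, sample(c("+", "-"), 1L))
        pos <- pos + geneLen
    }
    if (!arrayPlaced || length(gene_start) < 2L)
        stop("genome too short for the requested layout")
    features <- GRanges("synthetic_host",
                        IRanges(gene_start, gene_end), strand = gene_strand)
    S4Vectors::mcols(features)$gene_id <-
        sprintf("g%03d", seq_along(features))

    chars <- sample(bases, L, replace = TRUE, prob = composition)
    segment <- if (arrayStrand == "-") .revComp(locus) else locus
    array_end <- array_start + arrayLen - 1L
    chars[array_start:array_end] <- strsplit(segment, "")[[1L]]

    # spacer intervals on the genome (direct strand)
    if (arrayStrand == "+") {
        sp_g_start <- array_start + sp_locus_start - 1L
        sp_g_end <- sp_g_start + spacerLength - 1L
    } else {
        sp_g_end <- array_end - (sp_locus_start - 1L)
        sp_g_start <- sp_g_end - spacerLength + 1L
    }
    array <- CrisprArray(spacers, rep_seq, arrayStart = array_start,
                         arrayEnd = array_end,
                         spacerRanges = IRanges(sp_g_start, sp_g_end),
                         arrayStrand = arrayStrand)

    intergenic <- classifyIntergenic(features, L, circular)
    truth <- data.frame(plant_id = character(0), spacer_id = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), category = character(0),
                        n_mismatches = integer(0),
                        mismatch_positions = character(0),
                        pam = character(0))
    if (nPlants > 0L) {
        planted <- .plantProtospacers(chars, features, intergenic, array,
                                      spacers, nPlants, rho, plantStrands,
                                      regionWeights, mismatchRange, pam,
                                      pamFraction)
        chars <- planted$chars
        truth <- planted$truth
    }
    genome <- ScanGenome("synthetic_host", paste(chars, collapse = ""),
                         circular = circular, provenance = "host")
    list(genome = genome, features = features, array = array,
         intergenic = intergenic, truth = truth)
}

.plantProtospacers <- function(chars, features, intergenic, array, spacers,
                               nPlants, rho, plantStrands, regionWeights,
                               mismatchRange, pam, pamFraction) {
    bases <- c("A", "C", "G", "T")
    spacerLength <- nchar(spacers[[1L]])
    need <- spacerLength + 6L  # 3 nt clearance each side inside the region
    coding <- codingTiling(features)
    regions <- data.frame(
        start = c(IRanges::start(coding), IRanges::start(intergenic)),
        end = c(IRanges::end(coding), IRanges::end(intergenic)),
        category = c(rep("coding", length(coding)),
                     S4Vectors::mcols(intergenic)$category))
    regions <- regions[!is.na(regions$category), , drop = FALSE]
    regions$width <- regions$end - regions$start + 1L
    if (is.null(regionWeights)) {
        tot <- tapply(regions$width, regions$category, sum)
        regionWeights <- setNames(as.numeric(tot), names(tot))
    }
    regionWeights <- regionWeights[regionWeights > 0]
    if (!length(regionWeights) || any(regionWeights < 0))
        stop("region weights must be non-negative with positive sum")

    occupied <- IRanges(array@arrayStart - 3L, array@arrayEnd + 3L)
    truth <- vector("list", nPlants)
    for (p in seq_len(nPlants)) {
        sid <- names(spacers)[((p - 1L) %% length(spacers)) + 1L]
        strand <- if (!is.null(plantStrands)) plantStrands[p]
                  else if (stats::runif(1L) < rho) "reverse" else "direct"
        placed <- FALSE
        for (try_ in seq_len(500L)) {
            categ <- .sample1(names(regionWeights), prob = regionWeights)
            cand <- regions[regions$category == categ &
                            regions$width >= need, , drop = FALSE]
            if (!nrow(cand)) next
            ri <- sample.int(nrow(cand), 1L, prob = cand$width)
            s <- cand$start[ri] + 3L +
                sample.int(cand$width[ri] - need + 1L, 1L) - 1L
            e <- s + spacerLength - 1L
            ext <- IRanges(s - 3L, e + 3L)
            if (any(IRanges::overlapsAny(ext, occupied))) next
            # mutate interior positions so the full-length alignment at
            # the planted locus stays optimal
            m <- .sample1(mismatchRange)
            sp <- strsplit(spacers[[sid]], "")[[1L]]
            mpos <- if (m > 0L)
                sort(sample(4:(spacerLength - 3L), m)) else integer(0)
            for (mp in mpos)
                sp[mp] <- sample(setdiff(bases, sp[mp]), 1L)
            proto <- paste(sp, collapse = "")
            if (strand == "direct") {
                chars[s:e] <- sp
            } else {
                chars[s:e] <- strsplit(.revComp(proto), "")[[1L]]
            }
            pam_here <- !is.null(pam) && stats::runif(1L) < pamFraction
            if (pam_here) {
                if (strand == "direct") {
                    chars[(s - 3L):(s - 1L)] <-
                        strsplit(.complementStr(pam), "")[[1L]]
                } else {
                    chars[(e + 1L):(e + 3L)] <-
                        rev(strsplit(pam, "")[[1L]])
                }
            }
            occupied <- c(occupied, ext)
            truth[[p]] <- data.frame(
                plant_id = sprintf("P%03d", p), spacer_id = sid,
                strand = strand, start = s, end = e, category = categ,
                n_mismatches = m,
                mismatch_positions = paste(mpos, collapse = ","),
                pam = if (pam_here) pam else NA_character_)
            placed <- TRUE
            break
        }
        if (!placed)
            stop("could not place plant ", p,
                 ": genome too small for the plant table")
    }
    list(chars = chars, truth = do.call(rbind, truth))
}

#' Simulate phage-like genomes
#'
#' Independent random genomes of the stated composition, optionally with
#' planted protospacers (mutated spacer copies at random non-overlapping
#' loci, strand sampled with bias `rho`).
#'
#' @param n number of genomes.
#' @param genomeLength length of each genome (default 40000 nt, a
#'   typical dsDNA coliphage size).
#' @param composition named base probabilities.
#' @param spacers optional named spacer set to plant from.
#' @param nPlants plants per genome (default 0).
#' @param rho reverse-strand probability for plants.
#' @param mismatchRange mismatch counts sampled per plant.
#' @param seed RNG seed.
#'
#' @return A list of [ScanGenome-class] objects with provenance
#'   `"phage"`; when plants are requested the truth tables are attached
#'   as `attr(genome, "truth")`.
#' @export
simulatePhages <- function(n, genomeLength = 40000L,
                           composition = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                           spacers = NULL, nPlants = 0L, rho = 0.5,
                           mismatchRange = 0:2, seed = 1L) {
    stopifnot(n >= 1L)
    lapply(seq_len(n), function(i) {
        .withSeed(deriveSeed(seed, i), {
            chars <- sample(names(composition), genomeLength,
                            replace = TRUE, prob = composition)
            truth <- NULL
            if (nPlants > 0L && !is.null(spacers)) {
                spacerLength <- nchar(spacers[[1L]])
                occupied <- IRanges()
                rows <- list()
                for (p in seq_len(nPlants)) {
                    sid <- names(spacers)[((p - 1L) %%
                                           length(spacers)) + 1L]
                    strand <- if (stats::runif(1L) < rho) "reverse"
                              else "direct"
                    for (try_ in seq_len(200L)) {
                        s <- sample.int(genomeLength - spacerLength - 6L,
                                        1L) + 3L
                        e <- s + spacerLength - 1L
                        if (any(IRanges::overlapsAny(
                                IRanges(s - 3L, e + 3L), occupied))) next
                        m <- .sample1(mismatchRange)
                        sp <- strsplit(spacers[[sid]], "")[[1L]]
                        mpos <- if (m > 0L)
                            sort(sample(4:(spacerLength - 3L), m))
                            else integer(0)
                        for (mp in mpos)
                            sp[mp] <- sample(setdiff(c("A", "C", "G", "T"),
                                                     sp[mp]), 1L)
                        chars[s:e] <- if (strand == "direct") sp
                            else strsplit(.revComp(paste(sp, collapse = "")),
                                          "")[[1L]]
                        occupied <- c(occupied, IRanges(s - 3L, e + 3L))
                        rows[[p]] <- data.frame(
                            plant_id = sprintf("P%03d", p),
                            spacer_id = sid, strand = strand,
                            start = s, end = e, n_mismatches = m)
                        break
                    }
                }
                truth <- do.call(rbind, rows)
            }
            g <- ScanGenome(paste0("phage_", i),
                            paste(chars, collapse = ""),
                            circular = FALSE, provenance = "phage")
            if (!is.null(truth)) attr(g, "truth") <- truth
            g
        })
    })
}

#' Write a simulated host to the pipeline's input formats
#'
#' Emits exactly what [readGenome()] and the scan stage consume - a
#' round-trip test of the genome I/O layer: genome FASTA, gene GFF3,
#' array FASTA (repeat record first, then the spacers in order) and the
#' truth table as TSV.
#'
#' @param sim a [simulateHost()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulated <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "host.fasta"),
               gff = file.path(dir, "host.gff3"),
               array = file.path(dir, "array.fasta"),
               truth = file.path(dir, "truth.tsv"))
    seqs <- Biostrings::DNAStringSet(as.character(genomeSeq(sim$genome)))
    names(seqs) <- genomeId(sim$genome)
    Biostrings::writeXStringSet(seqs, paths["genome"])
    gr <- sim$features
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
    S4Vectors::mcols(gr)$source <- "spacerscan"
    rtracklayer::export(gr, paths["gff"], format = "gff3")
    arr <- c(Biostrings::DNAStringSet(as.character(repeatSeq(sim$array))),
             spacerSeqs(sim$array))
    names(arr)[1L] <- "repeat"
    Biostrings::writeXStringSet(arr, paths["array"])
    utils::write.table(sim$truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
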