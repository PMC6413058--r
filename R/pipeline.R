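#' @importFrom utils write.table packageVersion
NULL

# small FNV-1a style checksum of a deparsed object, for run manifests
.configHash <- function(x) {
    bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
    h <- 2166136261
    for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %%
        2^31
    sprintf("%08x", as.integer(h))
}

#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one flat list with
#' explicit defaults; all defaults are echoed into the run manifest, so
#' a run is fully described by its manifest.
#'
#' @param host path to the host genome FASTA (with `gff`) or GenBank
#'   file, or a [simulateHost()] result for an in-memory run.
#' @param gff GFF3 annotation path when `host` is a FASTA path.
#' @param arrayFasta array FASTA path (repeat record first, then
#'   spacers) when `host` is a file path.
#' @param phages optional list of [ScanGenome-class] phages or a
#'   multi-FASTA path.
#' @param k hits reported per strand (default 10).
#' @param scoring a [scoringScheme()].
#' @param nRandomizations randomized replicates for the background
#'   (default 30).
#' @param sigma background bound width in standard deviations (default
#'   3).
#' @param thresholds host threshold grid (default `1:19`).
#' @param pamReference optional path to a reference interference-PAM
#'   list ([readPamReference()]).
#' @param categories SAC/SAS categories to profile.
#' @param seed master seed; every random stage derives from it.
#'
#' @return A named list of class `spacerscanConfig`.
#' @export
pipelineConfig <- function(host = NULL, gff = NULL, arrayFasta = NULL,
                           phages = NULL, k = 10L,
                           scoring = scoringScheme(),
                           nRandomizations = 30L, sigma = 3,
                           thresholds = 1:19, pamReference = NULL,
                           categories = c("all", "coding", "intergenic",
                                          "RNA+", "RNA-", "divergent",
                                          "convergent", "upstream",
                                          "DC", "RC"),
                           seed = 1L) {
    structure(list(host = host, gff = gff, arrayFasta = arrayFasta,
                   phages = phages, k = as.integer(k), scoring = scoring,
                   nRandomizations = as.integer(nRandomizations),
                   sigma = sigma, thresholds = as.integer(thresholds),
                   pamReference = pamReference, categories = categories,
                   seed = as.integer(seed)),
              class = "spacerscanConfig")
}

.writeTsv <- function(df, path, header_lines) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header_lines), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# hit table in report coordinates (already 1-based internally)
.hitReport <- function(hits) {
    cols <- intersect(c("spacer_id", "genome_id", "provenance", "strand",
                        "g_start", "g_end", "score", "q_start",
                        "theoretical_start", "rank", "region_type",
                        "rna_category", "intergenic_category",
                        "genome_strand", "container_id",
                        "boundary_spanning"), names(hits))
    hits[, cols]
}

#' Run the end-to-end spacer self-targeting analysis
#'
#' Stages, in order: load or simulate the host (and phages), build the
#' randomized background, scan every genome with every spacer, exclude
#' CRISPR-locus self-hits, classify the retained hits, compute SAC/SAS
#' category profiles with background bounds and significance, run the
#' score-distribution tests, count PAM-position motifs and call
#' over/underrepresentation (plus reference-PAM overlap when a reference
#' list is configured), and write every table plus a run manifest to
#' `outDir`. Any stage error aborts with the stage name. A rerun with
#' the same config is bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#'
#' @return Invisibly, a list with the in-memory results (`hits`,
#'   `profiles`, `significance`, `scoreTests`, `motifCalls`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "spacerscanConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    warnings_log <- character(0)
    stage <- function(name, expr) {
        tryCatch(withCallingHandlers(expr, warning = function(w) {
            warnings_log <<- c(warnings_log,
                               paste0(name, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }), error = function(e) stop("stage '", name, "' failed: ",
                                     conditionMessage(e), call. = FALSE))
    }
    hash <- .configHash(config)
    hdr <- c(paste0("spacerscan ", utils::packageVersion("spacerscan")),
             paste0("seed: ", config$seed),
             paste0("config: ", hash))

    # -- load ---------------------------------------------------------------
    sim <- stage("load", {
        if (is.list(config$host) && !is.null(config$host$genome)) {
            config$host
        } else if (is.character(config$host)) {
            gio <- readGenome(config$host, format = "fasta",
                              gff = config$gff)
            arr <- readArrayFasta(config$arrayFasta)
            arr <- locateArray(arr, gio$genome)
            list(genome = gio$genome, features = gio$features, array = arr,
                 intergenic = classifyIntergenic(
                     gio$features, genomeLength(gio$genome),
                     isCircular(gio$genome)))
        } else stop("config$host must be a path or a simulateHost() result")
    })
    if (config$nRandomizations < 2L)
        stop("stage 'background' failed: background statistics need at ",
             "least 2 randomizations (config$nRandomizations >= 2)",
             call. = FALSE)

    # -- background ---------------------------------------------------------
    bg <- stage("background", makeBackground(
        sim$genome, sim$features, n = config$nRandomizations,
        seed = config$seed))

    # -- scan + classify ----------------------------------------------------
    L <- genomeLength(sim$genome)
    circ <- isCircular(sim$genome)
    scanOne <- function(g) {
        h <- scanSpacers(sim$array, g, k = config$k,
                         scoring = config$scoring)
        h <- excludeSelfHits(h, sim$array,
                             host = identical(provenance(g), "host"))
        classifyHits(h, sim$features, L, circ, intergenic = sim$intergenic)
    }
    hostHits <- stage("scan", scanOne(sim$genome))
    bgHits <- stage("scan", lapply(bg, scanOne))
    .writeTsv(.hitReport(hostHits), file.path(outDir, "hits_host.tsv"), hdr)

    # -- profiles -----------------------------------------------------------
    profiles <- stage("profile", {
        rows <- lapply(config$categories, function(cat_) {
            real <- categoryProfile(hostHits, cat_, config$thresholds)
            reps <- lapply(bgHits, categoryProfile, category = cat_,
                           thresholds = config$thresholds)
            bounds <- backgroundBounds(reps, sigma = config$sigma)
            sig <- profileSignificance(real, bounds)
            cbind(real, bounds[, c("bg_mean", "bg_sd", "lower", "upper")],
                  z = sig$z$z, p_overall = sig$p)
        })
        do.call(rbind, rows)
    })
    .writeTsv(profiles, file.path(outDir, "profiles.tsv"), hdr)

    # -- score-distribution tests ------------------------------------------
    scoreTests <- stage("score_tests", {
        bgScores <- unlist(lapply(bgHits, function(h) h$score))
        st <- scoreDistributionTests(hostHits$score, bgScores)
        list(host_vs_randomized = list(t_p = st$t_p, ks_p = st$ks_p,
                                       ks_stat = st$ks_stat))
    })

    # -- PAM motifs ---------------------------------------------------------
    motifs <- stage("pam", {
        ctx <- extractContext(hostHits, sim$genome, "adjacent3")
        real <- countMotifs(ctx)
        reps <- lapply(seq_along(bg), function(i) countMotifs(
            extractContext(bgHits[[i]], bg[[i]], "adjacent3")))
        calls <- motifCalls(real, reps)
        overlap <- NA_real_
        if (!is.null(config$pamReference))
            overlap <- pamOverlap(calls,
                                  readPamReference(config$pamReference))
        list(real = real, calls = calls, overlap = overlap)
    })
    .writeTsv(motifs$calls, file.path(outDir, "motif_calls.tsv"), hdr)

    # -- manifest -----------------------------------------------------------
    cfg_echo <- config
    cfg_echo$host <- if (is.character(config$host)) config$host
                     else "<in-memory simulateHost() object>"
    manifest <- list(
        package = as.character(utils::packageVersion("spacerscan")),
        seed = config$seed, config_hash = hash,
        config = cfg_echo[setdiff(names(cfg_echo), "phages")],
        n_hits_host = nrow(hostHits),
        n_randomizations = length(bg),
        score_tests = scoreTests,
        pam_overlap = motifs$overlap,
        warnings = warnings_log)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null", pretty = TRUE)
    invisible(list(hits = hostHits, backgroundHits = bgHits,
                   profiles = profiles, scoreTests = scoreTests,
                   motifCalls = motifs$calls, manifest = manifest))
}

#' Read a CRISPR array from a two-part FASTA
#'
#' Format emitted by [writeSimulated()]: the first record is the repeat,
#' the remaining records are the spacers in leader-proximal order.
#'
#' @param path array FASTA path.
#' @param arrayStart,arrayEnd,arrayStrand optional genomic coordinates
#'   of the array locus on the host genome (required for self-hit
#'   exclusion when scanning a host).
#' @return A [CrisprArray-class].
#' @export
readArrayFasta <- function(path, arrayStart = 1L, arrayEnd = NA_integer_,
                           arrayStrand = "+") {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) < 2L)
        stop("array FASTA needs a repeat record plus >= 1 spacer record")
    CrisprArray(seqs[-1L], as.character(seqs[[1L]]),
                arrayStart = arrayStart, arrayEnd = arrayEnd,
                arrayStrand = arrayStrand)
}

#' Locate a CRISPR array locus on a host genome
#'
#' Reconstructs the array locus (repeat + spacer alternation) from a
#' [CrisprArray-class] and finds its exact occurrence on either strand
#' of the genome, filling in the array's genomic interval and strand -
#' required for self-hit exclusion when the array was read from a
#' stand-alone FASTA.
#'
#' @param array a [CrisprArray-class].
#' @param genome a [ScanGenome-class].
#' @return The array with `arrayStart`, `arrayEnd`, `arrayStrand` and
#'   the spacer intervals set. Errors when the locus is not found.
#' @export
locateArray <- function(array, genome) {
    sp <- vapply(seq_along(spacerSeqs(array)), function(i)
        as.character(spacerSeqs(array)[[i]]), character(1))
    rep_chr <- as.character(repeatSeq(array))
    locus <- paste0(rep_chr, paste0(sp, rep_chr, collapse = ""))
    gseq <- genomeSeq(genome)
    hit <- Biostrings::matchPattern(locus, gseq)
    strand <- "+"
    if (!length(hit)) {
        hit <- Biostrings::matchPattern(.revComp(locus), gseq)
        strand <- "-"
    }
    if (!length(hit))
        stop("array locus not found on the host genome")
    a1 <- start(hit)[1L]
    a2 <- end(hit)[1L]
    sp_local <- cumsum(c(nchar(rep_chr) + 1L,
                         utils::head(nchar(sp) + nchar(rep_chr),
                                     -1L)))
    if (strand == "+") {
        s1 <- a1 + sp_local - 1L
        s2 <- s1 + nchar(sp) - 1L
    } else {
        s2 <- a2 - (sp_local - 1L)
        s1 <- s2 - nchar(sp) + 1L
    }
    CrisprArray(spacerSeqs(array), rep_chr, arrayStart = a1, arrayEnd = a2,
                spacerRanges = IRanges(s1, s2), arrayStrand = strand)
}
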