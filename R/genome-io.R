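#' @importFrom Biostrings readDNAStringSet
#' @importFrom GenomicRanges GRanges reduce strand
#' @importFrom IRanges IRanges start end width gaps
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Read a genome and its gene annotation
#'
#' Reads either a GenBank flat file (sequence + features in one file) or a
#' FASTA file accompanied by a GFF3 annotation. Gene/CDS features are
#' returned as a [GenomicRanges::GRanges] with a `gene_id` metadata
#' column; coordinates are 1-based inclusive on the direct strand, the
#' convention used throughout the package.
#'
#' @param path path to the GenBank or FASTA file.
#' @param format `"genbank"` or `"fasta"`; `"fasta"` requires `gff`.
#' @param gff path to a GFF3 file (`##gff-version 3`, 1-based inclusive)
#'   when `format = "fasta"`.
#' @param provenance provenance label for the returned genome.
#' @param circular override the topology (GenBank LOCUS topology is used
#'   when `NULL`).
#'
#' @return A list with elements `genome` (a [ScanGenome-class]) and
#'   `features` (a `GRanges` of gene features, sorted).
#' @seealso [classifyIntergenic()], [simulateHost()] which emits these
#'   formats.
#' @export
readGenome <- function(path, format = c("fasta", "genbank"), gff = NULL,
                       provenance = "host", circular = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "genbank") {
        parsed <- .parseGenbank(path)
        if (is.null(circular)) circular <- parsed$circular
        genome <- ScanGenome(parsed$id, parsed$sequence, circular = circular,
                             provenance = provenance)
        feats <- parsed$features
    } else {
        if (is.null(gff))
            stop("format 'fasta' requires a 'gff' annotation file")
        seqs <- readDNAStringSet(path)
        if (length(seqs) != 1L)
            stop("expected a single-record FASTA, got ", length(seqs),
                 " records in ", path)
        genome <- ScanGenome(sub("\\s.*$", "", names(seqs)[1L]),
                             toupper(as.character(seqs[[1L]])),
                             circular = isTRUE(circular),
                             provenance = provenance)
        feats <- .readGff3Genes(gff)
    }
    if (length(feats) && max(end(feats)) > genomeLength(genome))
        stop("feature beyond sequence end: ",
             mcols(feats)$gene_id[which.max(end(feats))])
    feats <- sort(feats, ignore.strand = TRUE)
    list(genome = genome, features = feats)
}

.readGff3Genes <- function(gff) {
    gr <- rtracklayer::import(gff, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "CDS")
    if (any(as.character(gr$type) == "gene"))
        keep <- as.character(gr$type) == "gene"
    gr <- gr[keep]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
    ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
    feats <- GRanges(seqnames = as.character(GenomicRanges::seqnames(gr)),
                     ranges = IRanges(start(gr), end(gr)),
                     strand = strand(gr))
    mcols(feats)$gene_id <- as.character(ids)
    feats
}

# Minimal GenBank flat-file parser: LOCUS topology, gene/CDS features with
# plain, complement() and join() locations, ORIGIN sequence block.
.parseGenbank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    locus <- grep("^LOCUS", lines, value = TRUE)
    if (!length(locus))
        stop("not a GenBank flat file (no LOCUS line): ", path)
    id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
    circular <- grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE)

    ori <- grep("^ORIGIN", lines)
    if (!length(ori))
        stop("GenBank record has no ORIGIN sequence block: ", path)
    seq_lines <- lines[(ori[1L] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence))
        stop("empty sequence in GenBank record: ", path)

    fstart <- grep("^FEATURES", lines)
    feats <- list()
    if (length(fstart)) {
        block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
        key_idx <- grep("^\\s{5}\\S", block)
        for (i in seq_along(key_idx)) {
            first <- block[key_idx[i]]
            key <- sub("^\\s{5}(\\S+).*$", "\\1", first)
            if (!key %in% c("gene", "CDS")) next
            to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L
                  else length(block)
            body <- block[key_idx[i]:to]
            loc <- sub("^\\s{5}\\S+\\s+", "", first)
            j <- 2L  # location may continue before the first qualifier
            while (j <= length(body) && !grepl("^\\s+/", body[j])) {
                loc <- paste0(loc, trimws(body[j])); j <- j + 1L
            }
            rng <- .parseGbLocation(loc)
            if (is.null(rng))
                stop("unparseable feature location '", loc, "' in ", path)
            qual <- paste(body, collapse = " ")
            gid <- .gbQualifier(qual, "gene")
            if (is.na(gid)) gid <- .gbQualifier(qual, "locus_tag")
            feats[[length(feats) + 1L]] <-
                list(key = key, start = rng$start, end = rng$end,
                     strand = rng$strand, gene_id = gid)
        }
    }
    features <- GRanges()
    if (length(feats)) {
        keys <- vapply(feats, `[[`, character(1), "key")
        use <- if (any(keys == "gene")) keys == "gene" else keys == "CDS"
        feats <- feats[use]
        ids <- vapply(feats, `[[`, character(1), "gene_id")
        ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
        features <- GRanges(id,
            IRanges(vapply(feats, `[[`, numeric(1), "start"),
                    vapply(feats, `[[`, numeric(1), "end")),
            strand = vapply(feats, `[[`, character(1), "strand"))
        mcols(features)$gene_id <- ids
    }
    list(id = id, sequence = sequence, circular = circular,
         features = features)
}

.parseGbLocation <- function(loc) {
    loc <- gsub("\\s+", "", loc)
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    nums <- as.numeric(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (!length(nums) || anyNA(nums)) return(NULL)
    list(start = min(nums), end = max(nums), strand = strand)
}

.gbQualifier <- function(text, name) {
    pat <- paste0("/", name, "=\"([^\"]+)\"")
    m <- regmatches(text, regexec(pat, text))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
}

#' Merge gene features into a strand-agnostic coding tiling
#'
#' Overlapping gene features are merged by interval union so that the
#' coding/intergenic partition of the genome is a true tiling. Strand
#' information for RNA+/- classification is taken from the individual
#' (unmerged) gene with the largest overlap with a hit, not from the
#' merged tiles.
#'
#' @param features a `GRanges` of gene features.
#' @return A `GRanges` of merged coding intervals, sorted, unstranded.
#' @export
codingTiling <- function(features) {
    if (!length(features)) return(GRanges())
    reduce(features, ignore.strand = TRUE)
}

#' Classify intergenic regions as divergent, convergent or upstream
#'
#' Every gap between consecutive (merged) coding intervals is emitted once
#' and categorized from the orientation of its flanking genes: upstream of
#' both flanking genes (left gene on `-`, right gene on `+`) is
#' *divergent*; downstream of both (left `+`, right `-`) is *convergent*;
#' both genes on the same strand leaves the gap upstream of exactly one
#' gene, *upstream*. On a circular genome the gap spanning the origin is
#' one region; on a linear genome a terminal gap is classified from its
#' single flanking gene (upstream when the gene points away from the
#' genome end, convergent otherwise).
#'
#' @param features `GRanges` of gene features (possibly overlapping; the
#'   flanking strand is taken from the outermost gene of each merged run).
#' @param genomeLength genome length in nucleotides.
#' @param circular logical; circular topology.
#'
#' @return A `GRanges` with metadata columns `category` (`"divergent"`,
#'   `"convergent"`, `"upstream"`), `left_gene_id` and `right_gene_id`
#'   (`NA` at linear genome ends). Regions tile the annotation gaps
#'   exactly. With zero features, a circular genome yields one
#'   whole-genome region with `category = NA`; a linear genome is an
#'   error.
#' @export
classifyIntergenic <- function(features, genomeLength, circular = FALSE) {
    genomeLength <- as.integer(genomeLength)
    if (!length(features)) {
        if (!circular)
            stop("cannot classify intergenic regions: no gene features ",
                 "on a linear genome")
        out <- GRanges("genome", IRanges(1L, genomeLength), strand = "*")
        mcols(out)$category <- NA_character_
        mcols(out)$left_gene_id <- NA_character_
        mcols(out)$right_gene_id <- NA_character_
        return(out)
    }
    merged <- codingTiling(features)
    seqn <- as.character(GenomicRanges::seqnames(features))[1L]
    # strand and id of the outermost original gene on each side of a tile
    edgeGene <- function(tile_start, tile_end, side) {
        inside <- start(features) >= tile_start & end(features) <= tile_end
        cand <- which(inside)
        if (side == "left") cand[which.min(start(features)[cand])]
        else cand[which.max(end(features)[cand])]
    }
    n <- length(merged)
    leftEdge <- vapply(seq_len(n), function(i)
        edgeGene(start(merged)[i], end(merged)[i], "left"), integer(1))
    rightEdge <- vapply(seq_len(n), function(i)
        edgeGene(start(merged)[i], end(merged)[i], "right"), integer(1))
    gstrand <- as.character(strand(features))
    gids <- mcols(features)$gene_id

    categorize <- function(ls, rs) {
        if (ls == "-" && rs == "+") "divergent"
        else if (ls == "+" && rs == "-") "convergent"
        else "upstream"
    }

    starts <- integer(0); ends <- integer(0)
    cats <- character(0); lid <- character(0); rid <- character(0)
    addRegion <- function(s, e, left_i, right_i) {
        # left_i/right_i index merged tiles; NA marks a linear genome end
        if (e < s) return()
        ls <- if (is.na(left_i)) NA_character_
              else gstrand[rightEdge[left_i]]
        rs <- if (is.na(right_i)) NA_character_
              else gstrand[leftEdge[right_i]]
        cat_ <- if (!is.na(ls) && !is.na(rs)) categorize(ls, rs)
                else if (is.na(ls)) (if (rs == "+") "upstream"
                                     else "convergent")
                else (if (ls == "-") "upstream" else "convergent")
        starts <<- c(starts, s); ends <<- c(ends, e)
        cats <<- c(cats, cat_)
        lid <<- c(lid, if (is.na(left_i)) NA_character_
                       else gids[rightEdge[left_i]])
        rid <<- c(rid, if (is.na(right_i)) NA_character_
                       else gids[leftEdge[right_i]])
    }

    for (i in seq_len(n - 1L))
        addRegion(end(merged)[i] + 1L, start(merged)[i + 1L] - 1L, i, i + 1L)
    if (circular) {
        # single origin-spanning region between last and first tile,
        # represented as up to two ranges sharing one category
        s1 <- end(merged)[n] + 1L
        e2 <- start(merged)[1L] - 1L
        if (s1 <= genomeLength || e2 >= 1L) {
            ls <- gstrand[rightEdge[n]]
            rs <- gstrand[leftEdge[1L]]
            cat_ <- categorize(ls, rs)
            if (s1 <= genomeLength) {
                starts <- c(starts, s1); ends <- c(ends, genomeLength)
                cats <- c(cats, cat_)
                lid <- c(lid, gids[rightEdge[n]])
                rid <- c(rid, gids[leftEdge[1L]])
            }
            if (e2 >= 1L) {
                starts <- c(starts, 1L); ends <- c(ends, e2)
                cats <- c(cats, cat_)
                lid <- c(lid, gids[rightEdge[n]])
                rid <- c(rid, gids[leftEdge[1L]])
            }
        }
    } else {
        addRegion(1L, start(merged)[1L] - 1L, NA_integer_, 1L)
        addRegion(end(merged)[n] + 1L, genomeLength, n, NA_integer_)
    }
    if (!length(starts)) {
        out <- GRanges()
        mcols(out)$category <- character(0)
        mcols(out)$left_gene_id <- character(0)
        mcols(out)$right_gene_id <- character(0)
        return(out)
    }
    o <- order(starts)
    out <- GRanges(seqn, IRanges(starts[o], ends[o]), strand = "*")
    mcols(out)$category <- cats[o]
    mcols(out)$left_gene_id <- lid[o]
    mcols(out)$right_gene_id <- rid[o]
    out
}

#' Split a CRISPR locus into repeats and spacers
#'
#' Locates copies of the repeat within a locus sequence by repeated local
#' alignment (exact and near-exact copies; near-exact means a local
#' alignment score of at least `minScore`) and returns the maximal
#' segments strictly between consecutive repeat copies as spacers,
#' numbered from the leader end.
#'
#' @param locus locus sequence (character or `DNAString`).
#' @param repeatSeq the repeat sequence.
#' @param leaderSide `"left"` or `"right"`: which end of the locus carries
#'   the leader; spacer S1 is leader-proximal.
#' @param minScore minimum local alignment score for a repeat copy. The
#'   default (`NULL`) uses 60% of the perfect repeat score
#'   (`0.6 * match * repeat length`): near-exact copies with a few
#'   mismatches clear it comfortably, while chance matches of spacer
#'   segments against the repeat (which routinely exceed the
#'   conservation-stage flank cutoff of 25 under this scoring) do not
#'   fragment the parse.
#' @param scoring a [scoringScheme()].
#' @param arrayStart genomic coordinate of the locus' first base, used to
#'   report spacer intervals on the genome (default 1: locus coordinates).
#' @param arrayStrand strand annotation carried into the result.
#'
#' @return A [CrisprArray-class].
#' @export
parseCrisprArray <- function(locus, repeatSeq, leaderSide = c("left", "right"),
                             minScore = NULL, scoring = scoringScheme(),
                             arrayStart = 1L, arrayStrand = "+") {
    leaderSide <- match.arg(leaderSide)
    locus_chr <- toupper(as.character(locus))
    rep_chr <- toupper(as.character(repeatSeq))
    if (is.null(minScore))
        minScore <- ceiling(0.6 * scoring$match * nchar(rep_chr))
    hits <- .swKBest(rep_chr, locus_chr, scoring,
                     k = nchar(locus_chr), minScore = minScore)
    if (nrow(hits) < 2L)
        stop("array parse error: fewer than 2 repeat copies found ",
             "(score >= ", minScore, ")")
    hits <- hits[order(hits[, "s_start"]), , drop = FALSE]
    sp_start <- hits[-nrow(hits), "s_end"] + 1L
    sp_end <- hits[-1L, "s_start"] - 1L
    keep <- sp_end >= sp_start
    if (any(!keep))
        warning(sum(!keep), " zero-length spacer(s) skipped")
    sp_start <- sp_start[keep]; sp_end <- sp_end[keep]
    if (!length(sp_start))
        stop("array parse error: no spacers between repeat copies")
    if (leaderSide == "right") {
        sp_start <- rev(sp_start); sp_end <- rev(sp_end)
    }
    seqs <- substring(locus_chr, sp_start, sp_end)
    names(seqs) <- paste0("S", seq_along(seqs))
    off <- as.integer(arrayStart) - 1L
    CrisprArray(seqs, rep_chr,
                arrayStart = as.integer(arrayStart),
                arrayEnd = off + nchar(locus_chr),
                spacerRanges = IRanges(off + sp_start, off + sp_end),
                arrayStrand = arrayStrand)
}
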