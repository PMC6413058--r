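#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<-
NULL

.PROVENANCES <- c("host", "phage", "randomized-host", "randomized-phage")

#' Genome container for the spacer scan
#'
#' A genome sequence together with the metadata every downstream stage
#' needs: an identifier, circular/linear topology, and a provenance label
#' that records whether the sequence is a real host chromosome, a phage
#' genome, or a composition-preserving randomization of either.
#'
#' @slot id single genome identifier.
#' @slot sequence a [Biostrings::DNAString] (upper case; IUPAC ambiguity
#'   codes are tolerated and score as mismatches in all alignments).
#' @slot circular logical scalar; `TRUE` for circular chromosomes.
#' @slot provenance one of `"host"`, `"phage"`, `"randomized-host"`,
#'   `"randomized-phage"`.
#'
#' @seealso [ScanGenome()] for construction, [scanSpacers()],
#'   [randomizeGenome()].
#' @export
setClass("ScanGenome",
    representation(id = "character", sequence = "DNAString",
                   circular = "logical", provenance = "character"))

setValidity("ScanGenome", function(object) {
    msg <- NULL
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@sequence) < 1L)
        msg <- c(msg, "genome sequence must be non-empty")
    if (length(object@circular) != 1L || is.na(object@circular))
        msg <- c(msg, "'circular' must be TRUE or FALSE")
    if (length(object@provenance) != 1L ||
        !object@provenance %in% .PROVENANCES)
        msg <- c(msg, paste0("'provenance' must be one of: ",
                             paste(.PROVENANCES, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a ScanGenome
#'
#' @param id genome identifier.
#' @param sequence a [Biostrings::DNAString], or anything coercible to one
#'   (character, `DNAStringSet` of length 1). Upper-cased on input.
#' @param circular logical; circular topology (default `FALSE`).
#' @param provenance `"host"`, `"phage"`, `"randomized-host"` or
#'   `"randomized-phage"`.
#'
#' @return A [ScanGenome-class] object.
#' @examples
#' g <- ScanGenome("chr", "ACGTACGT", provenance = "host")
#' genomeLength(g)
#' @export
ScanGenome <- function(id, sequence, circular = FALSE, provenance = "host") {
    if (!is(sequence, "DNAString"))
        sequence <- DNAString(toupper(as.character(sequence)[1L]))
    new("ScanGenome", id = as.character(id), sequence = sequence,
        circular = circular, provenance = provenance)
}

#' CRISPR array representation
#'
#' Holds the repeat sequence and the ordered spacers of a CRISPR array,
#' together with the array's interval on the host genome. Spacers are
#' numbered from the leader end: S1 is the leader-proximal ("youngest")
#' spacer.
#'
#' @slot arrayStart,arrayEnd 1-based inclusive interval of the whole array
#'   on the direct strand of the host genome.
#' @slot repeatSeq the repeat as a [Biostrings::DNAString].
#' @slot spacers a named [Biostrings::DNAStringSet] (`S1`, `S2`, ...),
#'   leader-proximal first, in array (crRNA-sense) orientation.
#' @slot spacerRanges an [IRanges::IRanges] of the spacers' intervals on
#'   the direct strand of the host genome (may be zero-length for arrays
#'   parsed from an isolated locus).
#' @slot arrayStrand `"+"` or `"-"`: the genome strand carrying the array
#'   sequence as written (spacer self-alignments fall on the opposite
#'   strand of the spacer reading when this is `"-"`).
#'
#' @seealso [CrisprArray()], [parseCrisprArray()], [excludeSelfHits()].
#' @export
setClass("CrisprArray",
    representation(arrayStart = "integer", arrayEnd = "integer",
                   repeatSeq = "DNAString", spacers = "DNAStringSet",
                   spacerRanges = "IRanges", arrayStrand = "character"))

setValidity("CrisprArray", function(object) {
    msg <- NULL
    if (object@arrayStart < 1L || object@arrayEnd < object@arrayStart)
        msg <- c(msg, "array interval must satisfy 1 <= start <= end")
    if (length(object@repeatSeq) < 1L)
        msg <- c(msg, "repeat sequence must be non-empty")
    if (length(object@spacers) < 1L)
        msg <- c(msg, "array must contain at least one spacer")
    if (length(object@spacerRanges) &&
        length(object@spacerRanges) != length(object@spacers))
        msg <- c(msg, "spacerRanges must match the number of spacers")
    if (length(object@spacerRanges) &&
        (min(start(object@spacerRanges)) < object@arrayStart ||
         max(end(object@spacerRanges)) > object@arrayEnd))
        msg <- c(msg, "array interval must contain all spacer intervals")
    if (!object@arrayStrand %in% c("+", "-"))
        msg <- c(msg, "'arrayStrand' must be \"+\" or \"-\"")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CrisprArray
#'
#' @param spacers named character vector or [Biostrings::DNAStringSet] of
#'   spacer sequences, leader-proximal (S1) first. Unnamed input is named
#'   `S1..Sn`.
#' @param repeatSeq the repeat sequence.
#' @param arrayStart,arrayEnd the array interval on the host genome
#'   (1-based inclusive). Defaults cover an isolated locus.
#' @param spacerRanges optional [IRanges::IRanges] of spacer intervals on
#'   the host genome.
#' @param arrayStrand `"+"` (default) or `"-"`.
#'
#' @return A [CrisprArray-class] object.
#' @examples
#' arr <- CrisprArray(c("ACGTACGTACGT", "TTTTGGGGCCCC"), "GAGTTCCCCGC")
#' spacerSeqs(arr)
#' @export
CrisprArray <- function(spacers, repeatSeq, arrayStart = 1L,
                        arrayEnd = NA_integer_,
                        spacerRanges = IRanges(), arrayStrand = "+") {
    if (!is(spacers, "DNAStringSet"))
        spacers <- DNAStringSet(toupper(as.character(spacers)))
    if (is.null(names(spacers)) || !all(nzchar(names(spacers))))
        names(spacers) <- paste0("S", seq_along(spacers))
    if (!is(repeatSeq, "DNAString"))
        repeatSeq <- DNAString(toupper(as.character(repeatSeq)[1L]))
    if (is.na(arrayEnd))
        arrayEnd <- arrayStart - 1L +
            (length(spacers) + 1L) * length(repeatSeq) +
            sum(lengths(spacers))
    out_of_range <- lengths(spacers) < 30L | lengths(spacers) > 35L
    if (any(out_of_range))
        message("spacer length outside the typical 30-35 nt range: ",
                paste(names(spacers)[out_of_range], collapse = ", "))
    new("CrisprArray", arrayStart = as.integer(arrayStart),
        arrayEnd = as.integer(arrayEnd), repeatSeq = repeatSeq,
        spacers = spacers, spacerRanges = spacerRanges,
        arrayStrand = arrayStrand)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn ScanGenome-class genome identifier.
#' @param x a `ScanGenome` or `CrisprArray`.
#' @export
genomeId <- function(x) x@id

#' @describeIn ScanGenome-class genome sequence as a `DNAString`.
#' @export
genomeSeq <- function(x) x@sequence

#' @describeIn ScanGenome-class genome length in nucleotides.
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn ScanGenome-class circular topology flag.
#' @export
isCircular <- function(x) x@circular

#' @describeIn ScanGenome-class provenance label.
#' @export
provenance <- function(x) x@provenance

#' @describeIn CrisprArray-class spacer sequences (named `DNAStringSet`).
#' @param x a `CrisprArray`.
#' @export
spacerSeqs <- function(x) x@spacers

#' @describeIn CrisprArray-class the repeat sequence.
#' @export
repeatSeq <- function(x) x@repeatSeq

#' @describeIn CrisprArray-class array interval on the host genome as an
#'   `IRanges` of length 1.
#' @export
arrayRange <- function(x) IRanges(x@arrayStart, x@arrayEnd)

#' @describeIn CrisprArray-class spacer intervals on the host genome.
#' @export
spacerRanges <- function(x) x@spacerRanges

setMethod("show", "ScanGenome", function(object) {
    cat("ScanGenome '", object@id, "': ", length(object@sequence), " nt, ",
        if (object@circular) "circular" else "linear",
        ", provenance=", object@provenance, "\n", sep = "")
})

setMethod("show", "CrisprArray", function(object) {
    cat("CrisprArray: ", length(object@spacers), " spacers, ",
        length(object@repeatSeq), " nt repeat, locus ",
        object@arrayStart, "-", object@arrayEnd,
        " (", object@arrayStrand, ")\n", sep = "")
    cat("  spacer lengths: ",
        paste(lengths(object@spacers), collapse = " "), "\n", sep = "")
})
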