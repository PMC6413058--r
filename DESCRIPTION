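Package: spacerscan
Title: Self-Targeting Analysis of CRISPR Spacers Against Host and Phage
    Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An exhaustive Smith-Waterman scan of Type I-E CRISPR spacers
    against annotated host genomes, phage genomes and
    composition-preserving genome randomizations. Reports the k best
    non-overlapping local alignments per strand (Waterman-Eggert
    declumping), classifies targets by coding/intergenic context, RNA+/-
    orientation, intergenic subcategory (divergent, convergent, upstream)
    and genome strand, computes spacer alignment count (SAC) and score
    (SAS) threshold profiles with randomized-background confidence
    bounds, detects overrepresented 3 nt motifs at the protospacer
    adjacent motif (PAM) position, and post-processes homology-search
    output for spacer/target conservation analysis. Includes a synthetic
    genome generator with planted protospacers for ground-truth
    validation of every stage.
License: GPL-3
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
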