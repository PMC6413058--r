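---
title: "Methods: scanning CRISPR spacers for host self-targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning CRISPR spacers for host self-targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the procedure

A Type I-E CRISPR array carries an ordered set of spacers (S1 nearest
the leader, the "youngest") whose crRNAs guide the Cascade interference
complex to complementary protospacers. If the system's dominant activity
were canonical immunity, spacers should resemble phage sequences; if it
regulates the host's own genes, high-scoring matches should concentrate
in the host chromosome, and in positions where Cascade binding can
interfere with transcription. `spacerscan` implements the computational
side of that question as a reusable pipeline:

1. **Scan.** Every spacer is aligned against both strands of every
   genome (host, phages, and randomized versions of each) by exhaustive
   Smith-Waterman dynamic programming, reporting the *k* best
   non-overlapping local alignments per strand (Waterman-Eggert
   declumping: each reported subject interval is masked before the next
   pass).
2. **Rank and exclude.** Per spacer and genome, the two strand lists
   are merged by descending score. On the host, the spacer's alignment
   to its own locus is a trivial perfect hit; it is reported at rank 1
   and then excluded, leaving `2k - 1` targets per spacer (19 at the
   default `k = 10`).
3. **Classify.** Each retained hit is labelled coding vs intergenic (by
   majority of aligned positions; exact ties go to coding), RNA+/RNA-
   within coding regions, divergent/convergent/upstream within
   intergenic regions, and DC/RC by genome strand.
4. **Profile.** For every category, SAC (sum of alignment counts) and
   SAS (mean alignment score) are computed per rank threshold
   `kappa = 1..19`: SAC at threshold 3 counts qualifying hits among each
   spacer's first 3 ranked alignments, summed over the array.
   Randomized-genome replicates give a per-threshold normal background
   (sample mean, n-1 sd) and 3-sigma confidence bounds; significance is
   reported as per-threshold z-scores plus one paired t-test of the real
   profile against the background means across the threshold grid.
5. **PAM.** Around each hit's *theoretical start* (see below) the 3 nt
   flanking motif is counted over all 64 triplets; Poisson fits to the
   replicate counts give central 99.73% bounds and over/under calls,
   and over-motifs can be intersected with a user-supplied list of
   experimentally confirmed interference PAMs.
6. **Conservation post-processing.** Tabular homology-search output
   (standard 12-column format) is filtered at E < 1e-3 (strict), hits
   are classified as CRISPR-array context when both 40 nt flanks align
   to the repeat with score >= 25, and spacer vs target hit-count
   distributions are compared with Poisson 3-sigma intervals.

The search itself (step 6's BLAST runs) is out of process by design:
the package consumes its output and provides the post-processing, which
is the analysis' own contribution.

# Alignment model and its knobs

* **Substitution scores**: +5 match / -4 mismatch, the ACGT core of the
  NUC44 matrix. IUPAC ambiguity codes are kept on input but score as
  mismatches against everything, including themselves - conservative,
  never inflating a score.
* **Gap model**: linear, -8 per gapped position, configurable
  (`scoringScheme()`). Under this permissive gap model chance local
  alignments of a 32-mer against tens of kilobases reach scores of
  60-80; planted near-exact protospacers score `5(L - m) - 4m` for
  `m` interior mismatches (152-160 for `L = 32`, `m <= 2`), so signal
  and noise are well separated.
* **Hits per strand** `k = 10`, merged to 20 per genome and spacer.
  Rank ties are broken deterministically: self-alignment first, then
  direct strand, then lower genome start. Inside the DP, traceback
  prefers diagonal over up over left and the best cell is the
  maximum-score cell with the smallest subject end - reruns are
  bit-identical.
* **Threshold grid**: 1..19 on the host (after self-hit exclusion),
  1..20 on phages (no self-hit exists there).
* **Randomizations**: 30 replicates by default; within every coding
  region and every intergenic region *independently*, the sequence is a
  uniform random permutation of that region's nucleotides, so
  per-region composition is conserved exactly. The shuffle unit is the
  single nucleotide; dinucleotide- or codon-preserving shuffles are a
  possible extension, not implemented. Phage genomes without annotation
  shuffle as one region. Replicate seeds derive from
  `(seed, replicate index)` so any replicate is reproducible alone.

## The self-hit and the 19-target scheme

On a host-provenance genome the array interval is masked during the
target search, so alignments to the CRISPR locus itself (the spacer's
own copy, the near-identical repeats, neighbouring spacers) never occupy
target slots; on the real host the spacer's self-alignment against the
locus is computed separately, reported as the rank-1 hit of its strand
(that strand then carries the self-hit plus its `k - 1` best targets),
and removed by `excludeSelfHits()`. This makes the retained count
exactly `2k - 1` per spacer by construction. Without the mask, a
genome only ~130x longer than its array would occasionally place a
chance target inside the array interval and lose it to the exclusion
step, making the retained count fluctuate between 18 and 19; on a
megabase-scale chromosome the distinction is invisible, but on
synthetic desk-scale genomes the masked design is the faithful version
of "the self-alignment is the one trivial hit".

Randomized host replicates are scanned with the same mask and no
self-hit, retaining `2k` hits; profiles only ever read ranks up to 19,
and score pools are composition-matched (10 direct + 9 reverse per
spacer on both sides) wherever real and randomized distributions are
compared.

## Theoretical start and PAM windows

The *theoretical start* of a hit is its actual alignment start extended
upstream by the unaligned spacer prefix (upstream = decreasing direct
coordinate for direct-strand hits, increasing for reverse). A hit whose
theoretical start falls outside the genome is flagged edge-truncated
and excluded from PAM analysis; a window that would run past a linear
genome end is skipped.

Three contexts anchor at the theoretical start: the adjacent 3 nt
(canonical interference-PAM position), the upstream 6 nt (counted as
overlapping 3-mer windows; switchable to non-overlapping), and the gap
segment between theoretical and actual start (length = the unaligned
prefix; empty for full-length alignments). All are read on the targeted
strand - the reverse complement of the strand carrying the hit, which
is the strand the crRNA base-pairs with - and reported 3'->5' by
default with a 5'->3' switch, because the flanking side and reading
convention of PAM reports vary between sources; the synthetic
generator writes its planted PAM in the default convention, so
planted-truth recovery exercises the orientation mapping on both
strands.

# The synthetic test bed

`simulateHost()` generates the study conditions: a linear genome
(default 100 kb, uniform composition) tiled by genes of 300-1500 nt
with random orientations separated by 60-260 nt gaps (~85% coding,
bacterial-like), an embedded CRISPR array (12 spacers of 32 nt between
13 copies of a 28 nt repeat - typical Type I-E dimensions - written on
the minus strand so self-alignments fall on the reverse strand, as for
an array annotated in crRNA sense), and optional planted protospacers:
mutated spacer copies with configurable strand bias `rho`,
region-category weights, per-plant mismatch counts, and an optional PAM
triplet written immediately upstream on the targeted strand. Mismatches
are placed at interior spacer positions so the planted locus remains
the optimal full-length alignment; every plant sits wholly inside one
region of its sampled category with 3 nt clearance, so truth categories
are crisp. `simulatePhages()` draws i.i.d. genomes (default 40 kb, a
typical dsDNA coliphage size) with the same optional planting.

What the generator does *not* emulate: real codon structure, operons,
GC skew, repeated elements, mobile DNA, or phylogenetic relatedness.
Passing the planted-truth tests therefore demonstrates that the
machinery recovers known statistical structure (strand bias, category
depletion, PAM enrichment) from data satisfying its assumptions - not
that any particular real genome exhibits that structure.

## Problem sizes used by the test suite

Chosen to keep the full suite within a few minutes while leaving each
statistic comfortably powered:

* alignment oracle equivalence: 200 random instances, query <= 40 nt,
  subject <= 500 nt, up to 4 declumping passes, exact agreement;
* hit-reporting and randomization invariants: the default 100 kb / 12
  spacer host, 30 replicates;
* planted-truth runs: 50 kb hosts with 30 replicates - strand bias
  `rho = 0.9` with 60 plants (z of SAC(RC) - SAC(DC) at threshold 10),
  and a convergent-weight-0 run with 19 plants per spacer on an
  intergenic-rich layout (gaps 300-700 nt) so the convergent background
  mean is large enough for its 3-sigma lower bound to sit above zero;
* null calibration: 20 runs on 12 kb hosts with 10 replicates each.

The convergent-depletion condition deserves a note: with a
bacterial-like 85% coding density, convergent gaps cover only ~4% of
the genome, the background convergent SAC at any threshold stays below
~9, and a mean below 9 can never exceed three of its own Poisson-scale
standard deviations - the lower bound is negative and *no* depletion,
however total, can cross it. Detecting convergent depletion at 3 sigma
therefore requires either a long threshold grid on a large genome or an
intergenic-rich layout; the test uses the latter, which is a property
of the statistic, not of the implementation.

# Numerical and design choices

* **Coordinates** are 1-based inclusive on the direct strand
  everywhere, the native convention of the Bioconductor containers the
  package is built on (IRanges/GRanges/Biostrings) and of its written
  reports.
* **Overlapping genes** are merged by strand-agnostic interval union
  for the coding/intergenic partition; the strand used for RNA+/-
  comes from the individual gene with the largest overlap with the hit.
  Boundary-spanning hits carry a flag so the majority-containment
  convention can be audited against a strict-containment one.
* **Intergenic categories** are a pure function of flanking gene
  strands; on a circular genome the origin-spanning gap is one region,
  and linear terminal gaps are classified from their single flanking
  gene (upstream when it points away from the end). Note that the
  categories are invariant under reverse-complementing the genome - a
  gene pointing away from a gap still points away afterwards - which
  the property tests assert.
* **Paired significance test**: the pairing unit is the threshold -
  real SAC vs background mean SAC across the grid - because the profile
  is the object of interest; the per-threshold z-scores are always
  reported alongside, and a degenerate pairing (identical profiles)
  returns p = 1 rather than an error.
* **Motif p-values**: pairing a single real count with n replicate
  counts reduces to a one-sample t-test of the replicate-minus-real
  differences, and is implemented and labelled as such. A motif with
  zero background mean and zero observations is not-significant by
  convention.
* **Array parsing** (`parseCrisprArray()`): repeat copies are located
  by repeated local alignment; the acceptance threshold defaults to 60%
  of the perfect repeat score (84 for a 28 nt repeat) rather than the
  conservation-stage flank cutoff of 25, because under this scoring
  scheme random 32-mers routinely reach score 25 against a 28-mer and a
  cutoff that low fragments every parse. Near-exact copies (a few
  mismatches) still clear 60% comfortably. The leader side is an
  explicit argument since S1-numbering depends on it.
* **Flank cutoff 25** in the conservation stage is kept as the default
  interface value, but users should know it is permissive: random 40 nt
  flanks score ~26-28 against a 28 nt repeat under this scheme (the
  package exposes `flankScoreDistribution()` to inspect this), so the
  in-array call is driven by the conjunction of *both* flanks and, in
  practice, by genuine repeats scoring >= 100. A stricter cutoff can be
  passed where the null matters.
* **PAM-wheel scores**: two columns are emitted - the count fraction
  (relative abundance), and the difference-based variant
  `(count - total)/total`, which is negative for every motif; both
  conventions circulate for wheel plots, so both are reported and
  neither is silently corrected into the other.
* **Degenerate inputs**: empty sequences are argument errors; fewer
  than 2 background replicates is an error (sd undefined); an empty
  category selection yields an absent (NA) SAS, never 0; zero-variance
  score pools make the t-test NA while the KS test is still computed.

# Known limitations

* The scan is exhaustive DP - no E-values, no seeded heuristics; cost
  grows as query x subject per declumping pass (with incremental
  recomputation after masking, in compiled code). Megabase genomes with
  hundreds of spacers are feasible but minutes-scale.
* Circular genomes are aligned linearly; alignments spanning the origin
  are not found. For a ~750 bp array in a megabase chromosome the
  probability that a true top-10 hit crosses the origin is negligible.
* The null model preserves composition only; any signal carried by
  higher-order sequence structure (dinucleotide bias, codon usage) will
  appear non-random against this background.
* The KS test on integer score pools involves ties, which makes its
  p-values slightly anticonservative; calibration tests therefore
  accept up to 2 failures at p > 0.01 across 20 null runs.
* Functional-enrichment analysis of targeted genes and any
  taxonomy-database resolution are out of scope; the conservation stage
  consumes externally produced search output and a user-supplied
  subject-to-taxon map.

# A worked miniature

```{r example, eval = FALSE}
library(spacerscan)

sim <- simulateHost(genomeLength = 20000L, nPlants = 20L, rho = 0.9,
                    seed = 7L)
hits <- excludeSelfHits(scanSpacers(sim$array, sim$genome), sim$array)
hits <- classifyHits(hits, sim$features, genomeLength(sim$genome),
                     intergenic = sim$intergenic)
table(hits$genome_strand)

bg <- makeBackground(sim$genome, sim$features, n = 30L, seed = 7L)
profiles <- categoryProfile(hits, "RC", thresholds = 1:19)
```

The same flow, file-based and with every table written out, is
available through `pipelineConfig()` + `runPipeline()`, or from a shell
via `inst/scripts/run-analysis.R`.
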