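---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomine)
```

This vignette records how each method in `mycomine` is defined, which
parameters matter, what the simulators do and do not emulate, and the design
choices made where the problem statement left the design genuinely open. The
package computes everything shown here at run time; no empirical claim in
this document goes beyond what the test suite and `scripts/acceptance.R`
themselves verify.

## CAZyme gene cluster calling

A cluster call operates on the *gene order* of a chromosome, not on raw
base-pair distances. After a deterministic ranking of genes (by start, ties
broken by end then lexicographic gene id), the distance between two genes is
the number of intergenic gaps crossed walking from one to the other: adjacent
genes are 1 apart, a gene is 0 from itself.

Two genes are linked when at least one of them is a CAZyme, the other is a
CAZyme or a signature gene (transporter or transcription factor), and their
gap distance is at most `max_gap` (default 2 — "within two intergenic
distances", i.e. at most one intervening gene). Components of this linkage
graph become clusters when they hold ≥ 3 CAZymes, or ≥ 2 CAZymes plus ≥ 1
signature gene.

Design choices worth recording:

* **Rank vs base pairs.** "Two intergenic distances" could also be read as a
  base-pair budget (the summed lengths of the intergenic intervals crossed).
  Rank distance is the default because the phrase counts *intergenic
  distances* as discrete steps, and comparable cluster callers (CGC-style
  tools for polysaccharide utilization loci) use gene-rank windows. The
  base-pair reading is available via `gap_mode = "bp"`, with a threshold
  defaulting to `max_gap` times the chromosome's median intergenic distance.
* **Which genes count toward ranks.** All annotated genes of any kind
  (including tRNA/rRNA/lncRNA models) occupy ranks; only the signature table
  decides roles. No exclusion rule was stated, and removing ncRNA genes from
  the order would silently shrink gaps.
* **Role exclusivity.** A gene tagged both CAZyme and transporter counts as
  CAZyme only (precedence cazyme > transporter > transcription factor), so a
  single gene can never satisfy both membership thresholds at once.
* **Signature bridging.** A signature gene linked to two CAZymes that are
  themselves 4 gaps apart merges them into one component (transitive
  closure). This is deliberate: the signature gene is within the stated
  distance of each CAZyme, and clusters are components, not windows.
* **Determinism.** Clusters are reported in coordinate order with ids
  `<chrom>:CGC<n>`; strand never enters any distance computation.

`cazgc_oracle()` re-derives the calls by building the full pairwise linkage
matrix from coordinates and extracting components with `igraph` — a
completely separate code path from the scanning union–find in
`predict_cazgc()`. The test suite proves set equality of member lists on
1,000 seeded random chromosomes of up to 20 genes, and `validate_cazgc()`
re-checks every reported cluster against the membership, linkage and span
invariants independently of the caller.

## Telomeres

`detect_telomeres()` counts the longest run of exact tandem copies of the
motif (`TTAGGG` at the 3′ terminus, its reverse complement `CCCTAA` at the
5′ terminus) within a terminal window. Parameters: `terminal_window`
(default 200 bp — generous for telomeric arrays while staying clear of
subtelomeric repeats) and `min_copies` (default 3) for the presence flag.
The motif is a stated biological fact; the copy threshold is not, so it is a
parameter with a conservative default. Reverse-complementing a chromosome
swaps the two terminal calls exactly, which the suite checks as a property.

## Centromere candidates

Centromeres of many basidiomycete chromosomes are long, gene-free,
retrotransposon-rich and transcriptionally quiet. The candidate on each
chromosome is the single longest interval containing no *protein-coding*
gene — non-coding gene models do not break an interval, since the defining
absence is of ORFs. Intervals considered are those between consecutive
protein-coding genes plus the two terminal intervals (`include_terminal =
TRUE` by default; terminal candidates are flagged so telomere-adjacent gaps
can be screened out downstream). Ties go to the leftmost interval.

Two evidence channels are attached, neither thresholded into the call
itself:

* `rt_fraction` — fraction of the interval covered by the union of
  confidence-filtered repeat hits. "Mostly repeats" is reported as a number;
  `rt_dominant` flags ≥ 0.5 for convenience, since no published cutoff
  exists.
* `expr_ratio` — mean RNA-seq depth inside the interval over the mean of two
  flanking regions. The flank length defaults to the candidate's own length
  (no flank length is stated anywhere; equal-length flanks make the ratio
  scale-free), clipped at chromosome ends, and is configurable.

Depth is aggregated from windowed tracks with windows weighted by their
overlap with the interval, so window size does not bias boundaries.

## Mitogenome comparison

`mito_compare()` computes a banded global alignment with unit edit costs in
compiled code (band half-width defaulting to `max(32, 4×|Δlength|)`; the
band must cover the length difference or the call errors out). The traceback
prefers diagonal over deletion over insertion, giving a deterministic
decomposition into substitutions, insertions and deletions. The per-base
rate divides total differences by the longer length and is displayed at 3
significant digits, the convention under which one difference across a
115,207 bp pair prints as 8.68 × 10⁻⁶.

Because mitogenomes are circular, the second sequence is first rotated to
the offset where the first kilobase of the first sequence anchors best
(exact match, then up to 100 mismatches); if no anchor exists the sequences
are compared as given, with a warning. Tests cross-check the banded result
against `utils::adist()` — an independent full-matrix implementation — and
verify the symmetry property (substitution counts equal under argument
exchange; insertions and deletions swap).

## Repeat filtering and density

The confidence filter keeps hits with length ≥ 140 bp **and**
Smith–Waterman score ≥ 450; the two thresholds are conjunctive and the
filter is idempotent and monotone in both. Density tracks report the
per-window fraction of bases covered by the *union* of hits (merged first,
so duplicated or split hits change nothing); the final window is clipped to
the chromosome end. Class assignment keys on RepeatMasker class strings:
LTR/LINE/SINE → class I, DNA → class II, everything else (simple repeats,
low complexity, unknown) → other; the class concepts are standard but this
specific string mapping is the package's own, so it is centralised in
`repeat_class_of()`.

## Expression statistics

RPK divides counts by transcript length in kilobases — the "per kilobase" in
TPM's own name fixes the unit even where a formula is quoted without one.
TPM renormalises RPK to a million per sample; FPKM uses the standard
`count × 10⁹ / (length × library size)` definition.

Differential calls pool counts within each group and test the 2×2 table
(gene vs rest-of-library, group A vs group B) with a two-sided Fisher exact
test: the sum of hypergeometric probabilities not exceeding the observed
one, with the conventional `1 + 1e-7` relative tolerance for floating-point
ties. The implementation is a vectorised `dhyper` tail sum; the tests
compare it to an independent `lchoose`-based enumeration (to 1e-12 over
every table with both margins ≤ 60) and to `stats::fisher.test`. Pooling
treats biological replicates as one library, which understates
between-replicate dispersion; the fold-change and expression-floor gates are
what keep the false-call rate low, and the planted-null simulation in the
suite confirms calls stay within binomial tolerance of zero. A
negative-binomial test (e.g. edgeR's) can be substituted upstream of the
calling rules by replacing the p-value column before thresholding.

Multiple testing uses Benjamini–Hochberg step-up (`stats::p.adjust`); the
procedure was unspecified, and BH is the field default for RNA-seq FDR.

A gene is `up` when fold change (ratio of group-mean TPMs) ≥ `fc` (3),
the FDR (not the raw p, by default — a `use_fdr = FALSE` flag restores the
raw-p reading) is below `alpha` (0.05), and the larger group-mean TPM
exceeds `tpm_floor` (0.5). Fold change on TPM rather than raw or normalised
counts is a choice; TPM is the scale on which the expression floor is
defined, so both gates live on one scale. Zero-over-zero is `NaN` and never
called; nonzero-over-zero is `+Inf` and passes the fold gate with the TPM
floor as the guard; a `pseudocount` option replaces this convention.

Fruiting-related genes (FRGs) are genes up-regulated in fruiting bodies
against *both* vegetative states (monokaryon and dikaryon contrasts) by
default — the stricter reading of an "or … respectively" phrasing;
`require_both = FALSE` gives the union. The ortholog-overlap partition
assigns each FRG the first matching class — FB-initiation ortholog,
FB-development ortholog, other ortholog, species-specific — with initiation
taking precedence so the four classes are disjoint and exhaustive.

## Filter cascades

The lncRNA cascade applies, in order: non-gene locus, length ≥ 200 nt,
FPKM > 1 (the boundary value is excluded), non-coding by the three
coding-potential evaluations, no Pfam domain, support from ≥ 3 lncRNA
predictors. The length and FPKM rules are phrased jointly ("length < 200 and
FPKM ≤ 1 were excluded") but applied as independent exclusions by default:
the conjunctive reading would retain a 100-nt high-FPKM transcript, which
contradicts the ≥ 200 nt definition of a lncRNA. `conjunctive = TRUE`
restores the literal reading. "Removed according to the evaluations of three
tools" is read conservatively: any tool calling the transcript coding
removes it (`coding_rule = "majority"` relaxes this to two of three).
Whether the "≥ 3 prediction tools" are the same three coding-potential tools
is unknowable from the description, so predictor support is an independent
count supplied in the evidence table.

Each row is excluded at the first failing stage, so the per-stage tallies
plus the accepted count always sum to the input size — an invariant the
tests assert on every fixture.

The effector rule keeps predicted secreted proteins — signal peptide
present, zero transmembrane domains, no GPI anchor — strictly shorter than
300 amino acids.

## What the simulators emulate

`simulate_genome()` produces a scaled-down multi-chromosome genome — by
default 3 chromosomes of roughly 100–200 kb with 60 genes each, sizes chosen
to keep full-suite runs fast while exercising every structural feature:

* telomeric tandem arrays (3–9 copies per terminus) with guard bases so the
  planted copy number is exactly the maximal run in the terminal window;
* one 30 kb ORF-free gap per chromosome tiled to 80% with high-scoring
  Gypsy hits (the planted centromere), with background repeat hits kept out
  of it and depth windows over it zeroed, so the true repeat fraction and
  expression ratio are exact by construction;
* background repeat hits whose lengths (60–400 bp) and scores (200–900)
  straddle the 140/450 confidence thresholds;
* planted clusters satisfying the calling rules by construction and decoys
  violating exactly one rule each (membership or spacing), with ≥ 4 spacer
  genes isolating every planted structure.

Background sequence is i.i.d. uniform ACGT and repeat hits are
coordinate-tagged rather than sequence-realistic: no downstream stage reads
repeat sequence content, so sequence realism would add cost without adding
test power. Consequently, passing tests demonstrate correctness of the
*rules and arithmetic* on cleanly planted features; they do not demonstrate
robustness to ragged real-world annotation (fragmented gene models, nested
repeats, degraded telomeres), which the package leaves to the caller's
judgement.

`simulate_counts()` mirrors a three-group mushroom developmental design — 4
monokaryon, 2 dikaryon and 3 fruiting-body samples — with log-normal
baseline means (median 200 counts), negative-binomial dispersion 0.1 (a
standard value for RNA-seq biological replicates; 0 gives Poisson), per-
sample log-normal size factors, and a planted set of fruiting-body
up-regulated genes at a fixed fold factor of 6. The fold sits comfortably
above the calling threshold of 3 so that recovery measures the method rather
than boundary noise; genes planted at exactly the threshold would be missed
half the time for purely stochastic reasons, which is a property of the
threshold, not of the implementation.

`simulate_mito_pair()` separates planted edits by at least 50 bp so the
planted operation counts are the unique minimal decomposition;
`simulate_depth_track()` plants a 38-fold amplified block with Poisson depth
noise and enough single-copy windows (300) that the estimator's sampling
error is well under the 5% recovery tolerance used in tests.

All generators draw every random number under the seed in their spec and
restore the caller's RNG state afterwards.

## Numerical conventions

* Coordinates are 1-based inclusive throughout (GFF3 convention); only BED
  export converts to 0-based half-open.
* FASTA is written at 60 columns, so write→read→write round-trips are
  byte-identical.
* Fisher p-values are capped at 1 after summation; ties in the two-sided sum
  use the `1 + 1e-7` relative tolerance shared with `stats::fisher.test`.
* Per-base difference rates are displayed at 3 significant digits; all other
  reported numbers are unrounded.
* Percentages in coverage reports are rounded to one decimal, matching the
  convention in which 254 of 666 prints as 38.1%.

## Problem sizes

The test suite runs the caller-vs-reference equivalence on 1,000 random
chromosomes, the Fisher comparison on every 2×2 table with margins ≤ 60
(about 3.6 million tables), the planted-null simulation on 20 seeds × 500
genes, and feature recovery on several full simulated genomes; the whole
suite completes in a few minutes on one CPU, as does
`scripts/acceptance.R`. These sizes were chosen as the smallest that make
the statistical assertions sharp (binomial tolerances shrink with n) while
keeping iteration fast.

## Known limitations

* The Fisher test on pooled counts is not a replicate-aware test; it is the
  stated statistical core here, with the fold and floor gates carrying the
  burden of specificity. For designs with strong between-replicate
  variation, substitute a negative-binomial p-value upstream of the calling
  rules.
* Cluster calling has no base-pair cap in rank mode: two CAZymes separated
  by one intervening gene link regardless of physical distance. The `bp`
  mode exists precisely for annotations with pathological intergenic spans.
* Centromere candidates are defined per chromosome; chromosomes whose true
  centromere is gene-containing (or whose assembly collapses the region)
  will yield a wrong but well-formed candidate — the evidence columns, not
  the interval itself, are the basis for acceptance.
* `benchmark_cazgc()` reproduces published per-genome cluster counts only
  when the corresponding deposited annotations and signature tables are
  supplied by the user; they are not redistributed with the package.
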