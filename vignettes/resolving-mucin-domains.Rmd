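---
title: "Resolving tandem-repeat mucin domains: methods and design"
author: "mucintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving tandem-repeat mucin domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucintr)
```

## The locus and its difficulty

A gel-forming mucin carries its PTS domain on one large exon organised
as an array of tandem-repeat (TR) units — typically a ~23-amino-acid
proline/threonine/serine motif repeated tens to a hundred times —
interleaved with conserved cysteine-rich CysD islands of roughly 100
amino acids. Because the units are nearly identical, short reads cannot
be placed within the array, and similarity search against the exon alone
cannot even anchor a long read unambiguously. Two structural features
rescue the problem: the single-copy introns flanking the exon, and the
CysD islands inside it, both unique enough to locate precisely. The
pipeline is built entirely around those anchors.

All intervals in this package are 0-based, half-open.

## Read recruitment

`locateAnchor()` runs a seed-and-extend search: exact 13-mer seeds,
densest-diagonal clustering, then a fitting alignment of the anchor
inside the clustered read window, on both strands. A hit is accepted at
identity ≥ 0.70 over ≥ 60% of the anchor — deliberately loose, because a
read at 30% per-base error still shows only ~70% alignment identity to
its own locus. Classification follows the anchor pattern: FULL (both
introns), TYPE I (upstream intron + CysD delimiter), TYPE II (delimiter
+ downstream intron). FULL + TYPE I reads build the upstream consensus,
FULL + TYPE II the downstream one; `countUsableReads()` is exactly this
bookkeeping. The two parts are split and later stitched at the
delimiter's **last cysteine codon**, so both parts retain the full
island and overlap across it.

The recruitment aligner scores match +1, mismatch −1, gap −1. This is
intentionally *not* the zero-gap-penalty setting used for the consensus
alignment: with free gaps, a fitting alignment degenerates into a
longest-common-subsequence stretch whose span and identity are
meaningless as an anchor hit.

## Zero-gap-penalty alignment and majority consensus

The multiple alignment uses match +1, mismatch 0, gap 0
(`pipelineConfig()` defaults). With free gaps, a whole-unit difference
between two sequences aligns as one contiguous 69-column gap block
rather than interrupting a unit — the property the comparison stage
depends on. A negative mismatch would be pointless under gap 0 (a
mismatch could always be replaced by a gap pair at equal or better
score); mismatch 0 with a diagonal-first deterministic traceback keeps
substitutions in aligned columns, which SNP calling needs.

`buildMsa()` is a center-star construction: the center is the segment
with the highest summed shared-k-mer count; every other segment is
pairwise aligned to it and merged under "once a gap, always a gap",
with insertions at the same center position stacked left-aligned into
shared columns. `consensusByMajority()` takes, per column, the modal
symbol over A, C, G, T and gap among the rows whose aligned extent
covers the column, then drops the gap-won columns. Ties between a base
and gap go to the base (dropping is unrecoverable); ties among bases go
alphabetically. Both rules are independent of row order.

### Why one round of voting is not enough

A single center-star round uses a noisy read as the coordinate
scaffold, and its own errors scatter the other reads' votes; moreover,
score-equivalent indel placements inside homopolymer and short
tandem-motif runs split votes across columns. `refineConsensus()`
therefore:

1. re-aligns every read against the first-round consensus and re-votes
   (the "align the consensus back to all reads" step), with strict
   unit-cost edit scores — reads of one individual share the repeat
   count, so positional precision is what voting needs there;
2. normalizes indel placement by pushing every gap to the end of its
   homopolymer run (the alignment analogue of VCF variant
   normalization), so equivalent placements stack;
3. runs a **median-string tile polish**: the consensus is carved into
   ~9-base tiles whose boundaries snap outward to homopolymer run ends
   (a run is never split), every read contributes its own version of
   each tile via flank-anchored extraction, and the string minimizing
   the summed edit distance to all read versions — the maximum-likelihood
   local consensus under a symmetric error model — replaces the tile
   when it strictly improves the sum. Exact-string plurality fails here
   (at 10% error almost every 10-base read window is unique), but the
   median criterion pools all windows.

## Flagging and translation-guided repair

`realignAndFlag()` realigns each read to the consensus and, for every
homopolymer run, derives the read's supported version of the run from
the bases between its flanking aligned anchors. Where the modal
alternative differs from the consensus it emits a suspect: MISSING_BASE,
EXTRA_BASE, or (for content-only differences) SUBSTITUTION, with

* `evidence` — head-to-head support of the modal alternative against the
  consensus-agreeing reads, and
* `gain` — the median criterion: how much better the modal string
  explains *all* read windows than the consensus string does.

`correctFrameshifts()` repairs in two phases. In the majority phase a
cluster of nearby suspects (score-equivalent placements of one event)
applies its best alternative outright when `gain ≥ 2`; each applied edit
registers its inverse as a candidate. In the translation phase the exon
is translated from its anchored frame; at the first premature stop (or
an end-of-exon frame break) every candidate at or before the disruption
proposes its single-base edit, candidates are scored by the stop count
in a 200-codon look-ahead window, and an edit is applied only if it
strictly improves (fewer stops, or the right parity fix at the exon
end). Ties go to the best-supported candidate (gain, then evidence),
then the smallest position. The pipeline iterates flag → repair to a
fixed point, with each decided site locked across rounds so rounds
cannot oscillate.

The per-position accuracy of the result is bounded by the depth: a
position where `n` reads align is wrong only if all `n` reads fail
there, so with per-read error `p` in the assumed band `[0.15, 0.30]`
the accuracy lies in `[1 − 0.30^n, 1 − 0.15^n]` — `accuracyBounds()`
reports exactly this, displayed as percentages rounded half-up to two
decimals (a truncated display is available, since `1 − 0.15^7` rounds
to 100.00%).

## Decomposition and comparison

`translateExon()` applies the standard genetic code (internal stops are
rendered `*` and counted). `findCysD()` slides a CysD reference over the
protein allowing up to 10% substitutions and reports each island's span
and its last cysteine. Island references are configuration inputs: for
real loci they come from reference annotation, for simulated loci from
the generator's truth (`cysdReferences()`); nested architectures are
handled by locating all islands first and decomposing every inter-island
stretch independently.

Two decomposers cover the observed repeat architectures.
`decomposeByStartMotif()` cuts units at successive occurrences of a
start motif (the `PS` rule), skipping occurrences that would create a
unit outside `[min_unit, max_unit]` (defaults 4 and 40 amino acids — the
filter that decides how internal motif occurrences inside long units are
absorbed). `decomposePeriodic()` cuts greedily against a unit consensus:
every cut length within ±3 of the unit length is scored by alignment
(match +1, mismatch −1, gap −1, unit tail free) plus a two-residue
register bonus when the next position looks like a unit start — the
bonus is what disambiguates where a 24-residue variant ends and the next
unit begins. Cutting stops when the score falls below half the aligned
length; terminal truncated copies (prefix or suffix of the unit) are
accepted.

`compareDecompositions()` aligns the two unit lists as token sequences:
substitution cost 0 for units at ≥ 90% identity and `1 − identity`
below, gap 0.45 per unit — so a whole-unit indel is always preferred
over matching two units under ~55% identity, and (the reason for the
zero band) deleting a SNP-carrying unit is never cheaper than deleting a
pristine copy, which would otherwise scatter a copy-number event and
hide SNPs. Matched units yield residue-wise SNP records; unmatched runs
yield CNV events with signed copy delta. In a perfectly homogeneous
array the position of an indel run is inherently unidentifiable; the
deterministic diagonal-first traceback reports a canonical placement,
and the event count and delta are invariant.

## The single-T estimator

In the repeat-region DNA no adjacent T pair occurs; an observed `TT` is
a SNP and is collapsed to one event (`countTEvents()` counts maximal T
runs, reporting runs ≥ 2 as anomalies; the collapse generalizes the
doublet rule to any run length, the only consistent extension). The
event count therefore scales linearly with the repeat count, and
`estimateRepeatDelta()` divides an event difference by the calibrated
per-repeat rate, rounding half away from zero — the rounding mode
consistent with the reference worked example the estimator is checked
against (13 extra events at 3.58 per repeat → 4 extra repeats). Rate transfer across repeat motifs is
unsupported; `estimateRepeatCount()` warns when the query and
calibration unit templates share < 90% identity. Because frameshift
repair edits homopolymer runs and T runs of length ≥ 2 do not occur in
template DNA, the event count is invariant under the adjustment
(`verifyTInvariance()`) — which is why the estimator works on the *raw*
consensus, before any frameshift is fixed.

## The synthetic-data generator

`makeLocus()` builds intron – (HEAD | TR array with CysD islands | TAIL)
– intron. Protein blocks are encoded by a deterministic codon table
keyed by (residue, position-in-block mod 3), so identical units have
identical DNA and the repeat structure is exact at the DNA level. The
table guarantees that no `TT` doublet can occur — the estimator's
premise — while still carrying T-bearing codons (ACT, CCT, AGT, …), so
that, as in real PTS-coding DNA, a frameshifted reading frame soon hits
a stop codon and translation-guided repair has signal; an early table
that minimized T content made shifted frames nearly stop-free and
silently disabled that repair. Codons beginning with T (TGC, TGG, TAC)
are junction-guarded by swapping the preceding codon to a non-T-ending
variant. Phenylalanine (TTT/TTC only) cannot be encoded under the
constraint and is rejected. Each CysD island is generated independently
over a fixed cysteine scaffold, so islands are distinct and one of them
can serve as a unique delimiter anchor.

`simulateReads()` injects errors position-wise independently at total
rate `pTotal` with an indel-dominant mix (mismatch 0.25, insertion 0.42,
deletion 0.33 — the regime in which the homopolymer gap-placement
ambiguity actually arises); inside homopolymer runs the mix shifts
toward deletion by a factor 1.5, redistributively, so the total rate is
unchanged and the empirical error rate converges exactly to `pTotal`.
Strands are sampled evenly; each read carries its ground-truth interval.
The default total rate, 0.20, sits inside the assumed 0.15–0.30 band.
`deriveVariant()` plants whole-unit copy-number changes (contiguous
pristine copies) and single-codon SNPs at unit offsets ≥ 2 — never
inside the start motif — at globally distinct offsets and never in
inserted copies, so the planted truth is unambiguous for round-trip
comparison.

What the generator does *not* emulate: chimeric reads and adapter
artifacts, per-position quality variation, coverage biases, diploid
heterozygosity, and — most importantly — sequence divergence *between*
repeat units beyond planted SNPs and length variants. Real arrays are
slightly heterogeneous, which actually aids alignment registration;
passing tests on perfectly homogeneous arrays is therefore the harder
setting for consensus building but the easier one for decomposition.
Conclusions about real data should be drawn accordingly.

## Numerical choices and problem sizes

* Pairwise alignment is a banded Needleman–Wunsch (Rcpp) with
  deterministic traceback (diagonal > up > left) and optional free end
  gaps; the default band is `max(180, 0.03·L + 50)`, comfortably above
  the net indel drift of a same-locus read.
* Median tiles are 9 bases before run-snapping, with up to 4 passes at
  rotating offsets; a replacement must improve the distance sum by ≥ 1.
* Suspect flags require ≥ 2 supporting reads and ≥ 25% head-to-head
  evidence; outright application requires median gain ≥ 2.
* The test suite and the acceptance script exercise the full pipeline at
  a 101-unit locus (~9.7 kb with 1 kb introns) with 15 locus-spanning
  reads at 10% error — about 15–25 s per run — and scale the remaining
  checks to loci of 6–30 units.
* Empirically, the per-run probability of byte-exact exon recovery under
  those conditions is ~0.85–0.95 depending on the seed set; the residual
  failures are positions where eight or more of the fifteen reads
  genuinely vote a shortened homopolymer and the shifted frame happens
  to avoid stop codons for hundreds of bases — locally indistinguishable
  from truth. Deeper coverage removes them: the bound `1 − p^n`
  improves geometrically with every extra aligned read.

## Known limitations

* Recruitment thresholds (identity 0.70, coverage 0.60, k = 13) are
  package defaults exposed in the configuration, set so that recruitment
  still succeeds at 30% per-base read error; they are not fitted to any
  particular dataset.
* `findCysD()` matches without indels; an unpolished frameshift inside
  an island can hide it. The pipeline therefore decomposes only the
  polished exon.
* Mixed-length replacement suspects (a run whose modal alternative
  differs in both content and length) are left to the translation phase
  rather than flagged precisely.
* The estimator assumes the query and calibration domains share the
  repeat motif; T-affecting SNPs (T↔A/C/G) bias the event difference
  and are surfaced only as anomalies, not corrected.
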