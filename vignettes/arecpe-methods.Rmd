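---
title: "Scoring the ARE/CPE balance of 3'-UTRs: methods and design notes"
author: "arecpe package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the ARE/CPE balance of 3'-UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arecpe)
```

## The biological problem

During the macrophage response to lipopolysaccharide (LPS), the duration of
each transcript's expression is set largely post-transcriptionally, by the
balance of destabilizing and stabilizing *cis*-elements in its 3'-UTR.
AU-rich elements (AREs, built from AUUUA pentamers) recruit TTP and drive
deadenylation and decay of pro-inflammatory mRNAs in the late response;
cytoplasmic polyadenylation elements (CPEs, a U-rich motif family) recruit
CPEB proteins, which counteract deadenylation and sustain the expression of
anti-inflammatory feedback regulators. A transcript carrying both element
types behaves according to their relative numbers: an excess of AREs
predicts late downregulation, an excess of CPEs predicts sustained
expression. This package implements that quantitative framework: motif
counting, a dominance score, kinetic classification of LPS time courses,
RIP-seq-style target calling, the associated group statistics, and a
synthetic-data generator that makes the whole pipeline testable end to end.

## Motif counting

**AREs.** `countARE()` counts every start position at which `ATTTA` matches,
so overlapping repeats all count: a maximal run `A(TTTA)^k` contributes
exactly `k`. We count uncapped runs: the overlapping-start definition
generalizes naturally to arbitrarily long runs, and a cap would discard
signal from extreme UTRs (runs of up to 17 pentamers occur in real
transcripts).

**CPEs.** `countCPE()` scans seven motifs — `TTTTAT`, `TTTTAAT`, `TTTTAAAT`,
`TTTTACT`, `TTTTCAT`, `TTTTAAGT`, `TTTTGT` — over all start positions and
sums the occurrences. No two motifs in this set can match at the same start
(they differ within their shared prefix length), a property the test suite
asserts by brute force, so the plain sum never double-counts a start.
Distance-to-PAS rules are deliberately **not** applied in the count used for
scoring.

**Positional CPE calls.** `classifyCPEPositional()` implements the separate,
position-aware notion of a "CPE-containing" UTR: at least one CPE motif must
start within a configurable window (default 100 nt) upstream of a
polyadenylation signal (default hexamers `AATAAA`/`ATTAAA`, PAS required).
Published CPE predictors use calibrated, motif-specific optimal distances;
we expose one simple window because the original calibration is not
restated here, and we keep it configurable (`pasWindow`, `pas`,
`requirePAS`) so users can match any calibration they prefer.

**Conventions.** Sequences are canonicalized to the DNA alphabet (uppercase,
`U -> T`); `N` never participates in a match; only the sense strand is
scanned, since the motifs are defined on the mRNA. All match coordinates are
1-based and closed, the Biostrings/IRanges convention, so match width equals
motif length. Per gene, the longest annotated 3'-UTR isoform is the
reference sequence (`selectLongestUTR()`), with length ties broken by the
lexicographically smallest transcript id for determinism.

## The ARE:CPE score

For a gene with `nAre >= 1` AREs and `nCpe >= 1` CPEs,

    score = log2(nAre / nCpe)

Positive scores are ARE-dominant, negative CPE-dominant. Genes with a score
of exactly 0 are labelled `BALANCED` and belong to neither dominance group:
the defining inequalities are strict, so the boundary class is kept separate
rather than silently assigned. Genes lacking either element class are
excluded (`buildScoreTable()` reports how many and why) rather than rescued
with pseudocounts — a zero count makes the ratio meaningless, and the
downstream dual-element gene lists are defined by exclusion anyway. The
single-element contrast, `classifyAreLevel()`, splits genes at more than 4
AREs (`ARE_HIGH`) versus 4 or fewer (`ARE_LOW`).

## Kinetic classification

Expression time courses (hours 0, 1, 3, 6, 9 post LPS by default) are
handled on a linear abundance scale. Replicates are averaged per timepoint
first (`averageReplicates()`). Each gene's course is then divided by its
maximum (`peakNormalize()`), and the peak-normalized 9 h value is the
persistence statistic: above 0.5 the gene is `SUSTAINED`, below 0.5
`DOWNREGULATED`. The value 0.5 itself is assigned to `SUSTAINED` so that the
two strict inequalities still partition a gene list exhaustively; the
boundary is measure-zero for continuous data, so the choice is a tie-break,
not a tuning knob. `lateRatio()` provides the complementary 9 h / 6 h
statistic for late-phase comparisons, and `percentRemaining()` implements
actinomycin-D-style decay normalization (reference-gene division, time 0
set to 100%).

Group comparisons use the two-sided Mann-Whitney test (`compareGroups()`):
exact when both groups have at most 8 observations and no ties, normal
approximation with continuity and tie correction otherwise. Gene-set
activity per sample is summarized by `zscoreSignature()`: gene-wise z-scores
averaged over the set, minus the same average over *all* genes. The global
centering removes the association expected of a randomly chosen set, so the
all-genes signature is identically zero; zero-variance genes are dropped
with a warning rather than propagating undefined z-scores.

## Target calling

`callTargets()` reproduces the three-way union rule for RIP-seq enrichment
tables, with all comparisons strict: (1) Benjamini-Yekutieli adjusted
p < 0.02 and log2 IP/input fold change > 0.5; (2) raw p < 0.02 and fold
change > 1.2; or (3) maximal overlapping peak score > 500 and fold change
> 0.5. UTR regions with no overlapping peak carry `max_score = 0`. When
several regions map to one gene the strongest evidence is aggregated
per gene (maximum fold change and peak score, minimum p-values) before the
rule is applied — the calling rule is most naturally read per gene, and the
per-gene maximum is the conservative aggregation for a union-of-criteria
rule. The universe is the expressed transcriptome: genes with strictly more
than 10 input reads. `overlapStats()` and `classEnrichment()` (two-sided
Fisher's exact test, conditional maximum-likelihood odds ratio) provide the
set-level statistics.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known ground truth without any external download. It emulates the *shape*
of the real inputs, not their full biological complexity.

**Sequences.** `generateUTR()` plants the requested numbers of ARE and CPE
motifs (CPE motifs cycle through the seven-motif vocabulary), each flanked
by `C` guards, in uniform-ACGT background that is rejection-sampled free of
ARE/CPE/PAS motifs; an `AATAAA` PAS can be placed near the 3' end. The
assembled sequence is re-scanned with the package's own counters and rebuilt
until the planted counts are reproduced exactly, so junction artifacts
cannot leak into the truth table. Packing that cannot fit in the requested
length is an error, not a silent truncation.

**Kinetics.** `generateTimeCourse()` draws a lognormal baseline (meanlog
`log(50)`, sdlog 0.5), an induction fold (meanlog `log(8)`, sdlog 0.3)
peaking at 1, 3 or 6 h, and decays post-peak at

    k = max(0, k0 + alphaAre * nAre - alphaCpe * nCpe)   per hour

with defaults `k0 = 0.05`, `alphaAre = 0.04`, `alphaCpe = 0.05`, and
multiplicative lognormal noise (sdlog 0.1). The linear-in-counts decay law
is an artifact assumption chosen to make parameter-recovery tests
meaningful — it is not a mechanistic claim — and every constant is
exposed through `kineticParams()`. Setting `alphaAre = alphaCpe = 0` yields
the null model used for calibration tests.

**Enrichment tables.** `generateEnrichmentTable()` flags a fraction
(default 0.1) of genes as true targets; targets draw log2 fold changes from
Normal(1.5, 0.4) and raw p-values from Uniform(0, 5e-6), non-targets from
Normal(0, 0.3) and Uniform(0, 1); BY adjustment is then computed over the
whole table, and input reads are negative-binomial (mean 200, dispersion
0.5). The target p-value ceiling is deliberately far below the BY-adjusted
calling threshold: Benjamini-Yekutieli over ~10^3 rows inflates p-values by
roughly `n * H(n) / rank` (about 0.37 at these sizes for a uniform-over-
milliunits law), so genuinely bound UTRs must enter with raw p-values
orders of magnitude smaller — as they do in real RIP-seq enrichment
output — for the adjusted-p criterion to be exercised at all.

**Whole studies.** `generateStudy()` ties the three generators together
under one master seed, deriving per-component sub-seeds
(`seed * 1000003 + k mod 2^31 - 1`) so any component is independently
reproducible, and cross-references everything by gene id.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic genome-wide count distributions and
normalization artifacts (values are clean abundances, not read counts),
UTR isoform structure and alternative polyadenylation, sequence composition
beyond uniform background, motif context effects (secondary structure,
binding-site competition), and any coupling between binding (enrichment
truth) and kinetics. The directional-recovery tests demonstrate that the
analysis detects the planted effect, not that the effect has the planted
form in biology.

## Numerical and design choices

* Boundary handling: dominance and persistence boundaries are strict
  inequalities with explicit tie classes (`BALANCED`; 0.5 to `SUSTAINED`).
* All threshold comparisons in target calling are strict, matching their
  printed definitions.
* Degenerate inputs error early and descriptively: all-zero time courses,
  zero denominators, empty groups, p-values outside (0, 1], universes
  smaller than their target sets, invalid sequence characters (with
  position).
* Motif inactivation (`inactivateMotifs()`) mutates targeted matches to
  `G`/`C` under a seed, re-scans the whole sequence, and accepts only
  substitutions that kill the target without creating any new ARE/CPE match
  anywhere; an infeasible request fails after a bounded retry budget.
* Output tables are sorted by gene id and use a single TSV dialect
  (tab-separated, header, `"."` for missing), so reruns diff cleanly.

## Simulation sizes used by the test suite

The packaged tests validate the counters against brute-force all-offset
oracles on 1,000 random AT-rich sequences; Fisher's exact p against
exhaustive hypergeometric enumeration for all 2x2 tables with positive
margins and total n <= 12; Mann-Whitney against full permutation
enumeration for group sizes up to 7; directional recovery on 100 replicate
studies of 200 genes per dominance class (expecting the CPE-dominant class
to persist longer, p < 0.01, in at least 95 of them); null calibration on
600 replicate studies of 50 genes per class with motif effects switched off
(rejection rate within 2 points of the nominal 5%); and target-calling
sensitivity/false-positive rate on twenty 1,000-gene enrichment tables.
These sizes were chosen so each Monte-Carlo check has a comfortably small
standard error relative to its acceptance band.

## Known limitations

* The positional CPE rule is a single-window approximation of calibrated
  motif-to-PAS distance rules; results labelled `cpe_positional` should be
  read with the configured window in mind.
* The score treats all seven CPE motifs and all ARE pentamers as
  equipotent; no weighting by position, conservation, or motif strength.
* Kinetic classification assumes the supplied expression matrix is already
  normalized on a linear scale; no count-model normalization is performed.
* Benjamini-Yekutieli adjustment is computed only inside the synthetic
  generator; real enrichment tables are expected to arrive with `pv_by`
  precomputed by the upstream enrichment analysis.
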