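---
title: "CNV discovery and validation from array CGH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV discovery and validation from array CGH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayCNV)
```

## The problem

Two-color array comparative genomic hybridization (aCGH) co-hybridizes a
test and a reference genome onto a dense oligo array and reads out, per
probe, the log2 ratio of the two fluorescence channels. A diploid region
present at two copies in both genomes sits near log2 = 0; a heterozygous
deletion in the test sample sits near log2(1/2) = -1; a single-copy gain
near log2(3/2) ≈ +0.585. Copy-number variant (CNV) discovery is the task
of segmenting each sample's noisy probe track into copy-neutral and
aberrant intervals, and a survey across samples then aggregates the
per-sample calls into population-level CNV regions (CNVRs), quantifies
their reliability, and asks biological questions of them (gene content,
selective constraint, relatedness of samples).

`arrayCNV` implements this workflow at desk scale for the kind of design
used in livestock CNV surveys: a ~1M-probe array (mean probe interval
around 2.6 kb), a dozen test samples against one reference, sex-mismatched
hybridizations as a built-in error control, qPCR confirmation of selected
regions by relative quantification, and UPGMA clustering of samples on
their binary CNVR carrier profiles.

## Model and procedure

### Preprocessing

Each probe carries two intensities and two signal-to-noise ratios. The QC
filter keeps a probe only if *both* channels exceed intensity 50 and SNR
25 — strict inequalities, as such thresholds are conventionally printed.
Failing probes stay in the track (row counts are preserved) but are
excluded from every downstream statistic.

Intensity-dependent dye bias is removed by LOWESS: the log2 ratio is
regressed on the mean log2 intensity A = (log2 T + log2 R)/2 and the
fitted trend subtracted. The span default is 0.3, the conventional
two-color choice; the regression is on intensity only, not genomic
position, since positional waves are a separate artifact class that the
detection threshold absorbs at this noise level.

Probe noise is estimated by the derivative log-ratio spread (DLRS):
`sigma = median(|x[i+1] - x[i]|) / (0.6745 * sqrt(2))` within
chromosomes. Successive differencing cancels segment-level signal, so the
estimate is insensitive to aberrations (only their two boundary
differences contribute), and it is invariant to any constant shift of the
track. A floor of 1e-3 protects the score denominator on degenerate
(constant) tracks.

Centralization re-centers the track so the dominant copy-neutral state
sits at 0. The neutral state is *located* by the highest-density
histogram bin (width 0.01), and the shift is then *refined* as the
median of all probes within ±0.25 log2 of that bin: the histogram alone
cannot beat two or three bin widths of error on the flat peak of a
Gaussian, while the local median is symmetric around the neutral state,
converges at roughly sigma/sqrt(n), and still excludes aberrant states
(the nearest one, a single-copy gain, sits ~0.585 away). The subtraction
iterates until the shift falls below tolerance. Before the mode is
computed, intervals whose |interval score| reaches the detection
threshold are masked, so strong aberrations cannot drag the baseline;
when more than half the genome masks out, the neutral state is no longer
identifiable and the function warns and falls back to the unmasked mode.

### Segmentation: interval scores with a fuzzy zero

The detection statistic for an interval with probe values `x1..xn` is

    S = mean(x) / sqrt(sigma^2/n + sigma_g^2)

With `sigma_g = 0` this is the classical interval score
`sum(x)/(sigma*sqrt(n))` of maximal-scoring-segment detection. The global
spread term `sigma_g` is the *fuzzy zero*: for any fixed mean, S is
bounded by `mean/sigma_g` as n grows, so arbitrarily long runs of
near-zero mean can never clear the threshold. This family is an open
re-implementation of the ADM2-style detection used by commercial aCGH
software; that algorithm is proprietary, so segment boundaries are not
expected to be bit-identical to it, and all quantitative guarantees here
are stated against synthetic ground truth. The default
`sigma_g = 0.2 * sigma` keeps the correction proportional to array
quality; it can be disabled (`sigma_g = 0`).

Detection scans each chromosome's QC-passing probes exhaustively (a
compiled O(n^2) scan) for the highest-|S| interval; if it clears the
threshold (default 6, roughly a six-sigma event, which on a pure-noise
5,000-probe track yields essentially no calls), the interval is emitted
and the flanks are searched recursively. Ties on |S| break to the
leftmost, then shortest interval, so results are reproducible. Two
post-passes polish the greedy output: probe-adjacent same-direction
pieces are rejoined when the merged interval still clears the threshold
(the fuzzy zero otherwise favours the high-mean core of one long
aberration), and each boundary is re-fit with the classical score
(`sigma_g = 0`) inside a window clipped at neighbouring segments, which
restores breakpoint accuracy without re-admitting low-amplitude runs. A
coarse-to-fine "seeded" mode scores windows of 10 probes first and
refines only candidate neighbourhoods; the exact mode is the reference
and the seeded mode is checked against it.

High-confidence CNV calls then require at least 5 probes and |mean log2|
strictly above 0.5 — the stringent published post-filter that trades
sensitivity for a very low false-positive rate. The sex-mismatch control
quantifies that trade: hybridizing a male test against a female reference
makes all of chrX a known deletion, so any chrX call with positive mean
is a false positive, and FPR = 100 * (false length) / (chrX length x
arrays).

### CNVRs

CNVRs are the transitive union of calls overlapping by at least 1 bp on
the same chromosome (half-open intervals; abutting calls do not merge).
This is the common aggregation convention; the 1 bp criterion is the
package's documented choice where surveys typically leave it implicit.
Carrier frequency divides by the number of *test* samples (the reference
is not a sample). A region is typed "both" as soon as it contains at
least one gain and one loss member. chrY is excluded from catalogs by
default: male-vs-female designs make chrY calls control material, not
population variation. Catalog comparison counts a query CNVR as
overlapping when it shares ≥ 1 bp with any reference region;
length-percent uses the query catalog's own total length, and overlap
across several references is the union of the per-reference hit sets,
never their sum.

### qPCR confirmation

Relative quantification uses the 2^-ddCt method with duplicate wells
averaged on the Ct scale: dCt = Ct(target) - Ct(control amplicon) per
sample, ddCt = dCt(sample) - dCt(reference), and the copy ratio 2^-ddCt
is 1 at baseline, 1.5 for a single-copy gain, 0.5 for a heterozygous
loss. The classification cutoffs (gain ≥ 1.4, loss ≤ 0.7, both
inclusive) are explicit, configurable defaults; confirmation tables in
this field rarely print theirs. Note an intrinsic precision limit: with
duplicate wells at a per-well Ct sd of 0.1, the ddCt statistic has sd
≈ 0.1·√2 ≈ 0.14 cycles, while a 3-copy gain sits only log2(1.5/1.4)
≈ 0.10 cycles above the 1.4 cutoff — so single-copy gains cannot be
confirmed reliably at this precision (roughly a quarter will read
"normal"), whereas heterozygous losses (margin ≈ 0.49 cycles) and
homozygous-state changes (ratio 2.0 or ≤ 0.25) classify essentially
always. This asymmetry matches the field's experience that qPCR
confirmation of modest gains is the weak spot of such campaigns. Predictive-rate
accounting follows the published convention: a predicted carrier is
confirmed when its qPCR call matches the predicted direction (for
"both"-type regions, the sample's own call direction); a predicted
non-carrier is "confirmed" when qPCR nevertheless finds variation —
i.e. the negative rate measures apparent false negatives of the array,
the expected cost of the stringent call filter. Campaign summaries
row-average the per-assay rates (negatives over assays where the rate is
defined). Note the two averaging conventions that coexist in such
reports: the row average of per-assay positive rates (0.8971 on the
shipped worked-example table) is not the same quantity as a
sample-weighted average; the package implements the row-average
convention, which is the one its worked-example table reproduces
exactly, and does not attempt to reproduce prose figures computed under
unstated alternatives.

### Gene content and constraint

Gene overlap uses the same ≥ 1 bp half-open criterion; a gene is
"complete" when contained in a single CNVR. dN/dS ratios are consumed as
a prepared table (computing them from alignments is out of scope), and
CNVR genes are compared with non-CNVR genes by a Wilcoxon rank-sum test:
midranks with tie correction and a continuity-corrected normal
approximation, switching to exact enumeration of all labelings when both
groups have ≤ 8 observations (exactness where it is cheap, the standard
approximation elsewhere). Conserved single-copy genes require high
orthology confidence and identity strictly above 80% in every listed
species.

### Clustering

Samples are encoded as 0/1 CNVR carrier vectors. The default distance is
Jaccard — shared *absence* of a CNVR is weak evidence of relatedness, so
simple matching (which rewards shared absences) is available but not the
default. UPGMA merges the closest pair under size-weighted average
linkage; equal distances break on the lexicographically smallest pair of
cluster representative labels, making the tree reproducible. Merge
heights are ultrametric node heights (half the between-cluster
distance). Branch support is the ordinary bootstrap proportion (BP) over
resampled CNVR columns; multiscale (AU) corrections are deliberately out
of scope — BP is well-defined and sufficient for the structural claim
the workflow makes (group separation). The bootstrap default is 1,000
replicates at desk scale; 10,000 matches the published setting.

## The synthetic-data generator

The generator emulates the study conditions: a fixed probe map shared by
all samples (one array design) with exponential inter-probe gaps at a
2,632 bp mean interval; per-sample truth segments with integer copy
states (loss-heavy weights mirroring the ~2.6:1 loss/gain imbalance
typical of aCGH calls) whose expected log2 is log2(copy/2), floored at -4
for homozygous deletions because real arrays saturate rather than
diverge; Gaussian probe noise (default sd 0.15 — surveys do not print
their per-probe noise, and this value makes the 5-probe/0.5 filter
meaningful: a 5-probe aberration at |log2| = 0.5 scores ~7.5, just above
threshold); optional sinusoidal waves and intensity-dependent dye bias to
exercise normalization; ~1% engineered QC failures to exercise the
filter; sex-mismatched tracks with chrX at -1 and chrY at a configurable
gain; and qPCR Ct tables with Ct = const - log_eff(copy) + noise at
efficiency 2.0 (primers in such studies are required to sit in
[1.95, 2.10]), duplicate wells, and a single-copy control amplicon.

What it does **not** model: probe sequence composition, GC waves fitted
from real genomes, spatial slide artifacts, mosaic or fractional copy
states, and the reference genome's own CNVs. Tests passing on this
generator therefore demonstrate correctness of the statistical machinery
under the stated noise model, not calling accuracy on any particular
real hybridization.

## Numerical choices and degenerate inputs

- All coordinates are 0-based half-open internally; 1-based inclusive
  appears only in report companions, since printed survey tables use that
  convention.
- Every simulator takes one integer seed and touches no global RNG state.
- Noise floor 1e-3 (DLRS of a constant track), centering bin width 0.01
  log2, centering tolerance 1e-3, at most 10 centering iterations.
- Multimodal centering ties choose the smaller shift and warn.
- Empty intervals are score errors; empty truth gives a pure-noise track;
  an empty call set gives an empty catalog (not an error), while an empty
  *query* catalog in a comparison is an error (the percentage is
  undefined).
- Rates with zero denominators are reported as missing (the "—" of
  printed tables), never as 0.

## Problem sizes

The test suite and the acceptance script run everything on seeded
synthetic data sized for a laptop: recovery on a 40 Mb chromosome
(~15,000 probes, 40 planted segments), null calibration on 100
pure-noise ~5,000-probe tracks, oracle equivalence on 100 random ≤ 200-
probe tracks, 12-sample pipeline demos on a 30 Mb two-chromosome genome,
bootstrap support at 300-1,000 replicates, and rank-sum calibration on
5,000-10,000 simulated null datasets. These sizes were chosen so each
property is measured with enough replication to be stable under its
stated bound while the whole suite stays in the minutes range.

## Known limitations

- The ADM2 "bin" parameter and fuzzy-zero formula are not public; the
  seeding window and the `sigma_g` term here are documented
  interpretations, so published segment boundaries from commercial
  software will not be reproduced exactly.
- Per-probe quality weights are accepted but default to 1.
- No LiftOver between genome builds; catalog comparisons assume a shared
  assembly.
- GO/KEGG enrichment and ortholog-ID conversion depend on external
  services with versioned databases and are out of scope; the gene module
  stops at overlap lists, biotype tallies, and the rank-sum comparison.
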