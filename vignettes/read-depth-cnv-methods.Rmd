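---
title: "Read-depth CNV detection, CNVR merging and Vst divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

## The model

Read-depth CNV detection rests on one assumption: in a uniformly
sequenced diploid genome, the mean depth of a window is proportional to
the number of copies of that window the individual carries.  Dividing
each individual's per-window depth by that individual's median depth
puts the diploid state at normalized RD = 1.0, so copy numbers 0, 1, 2,
3, 4 are expected at RD 0, 0.5, 1.0, 1.5, 2.0.  The median — not the
mean — is the normalizer because the CNV windows themselves would bias
a mean; as long as fewer than half the windows are copy-number variant
(true by orders of magnitude in real genomes) the median is anchored on
diploid windows.  `normalize_depth()` records the per-individual STDEV
of normalized RD (population standard deviation, ddof = 0) after
scaling; a per-chromosome mode is available for sex chromosomes, which
are otherwise normalized by the same global rule.

Raw depth enters the package as a windows × individuals TSV
(`read_depth_matrix()`); how depth was computed from alignments (read
counts vs base coverage) is outside the contract.  GC correction is not
applied; a natural hook point is the raw matrix itself, which can be
rescaled before normalization.

## Calling parameters

All thresholds live in `calling_params()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `del_cutoff` / `dup_cutoff` | 0.65 / 1.35 | RD | empirical bounds between diploid noise and heterozygous states at 0.5 / 1.5 |
| `stdev_mult` | 2 | — | statistical criterion 1 ± 2·STDEV, per individual |
| `min_freq` | 0.05 | carriers/individuals | population support filter |
| `min_hom` | 3 | individuals | rescue for rare but unambiguous events |
| `hom_del_rd` / `hom_dup_rd` | 0.25 / 1.75 | RD | midpoints between copy numbers 0–1 and 3–4 |
| `merge_alpha` | 0.05 | — | adjacent-window Pearson merge level |

The two calling criteria are conjunctive: a noisy individual (large
STDEV) cannot call shallow events, and a quiet one cannot call events
inside the empirical diploid band.  "Carrier frequency" operationalizes
the population filter: carriers / individuals in the analysis group,
since read-depth states do not resolve alleles.  The homozygosity RD
cutoffs are a design choice (no published cutoff exists); midpoints
make them symmetric in copy number.  Candidate filtering runs per
population, so a variant common in one ecotype but absent elsewhere is
not diluted below `min_freq` by pooling; the per-population CNVR sets
are then reconciled by `population_cnvr_sets()`.

Windows whose across-individual mean raw depth is below 10% of the
grand mean are dropped before normalization (`filter_low_coverage()`);
these are unmappable or absent regions whose ratios are dominated by
noise.  The 10% threshold is configurable.

## Merging rules and numerical choices

Adjacent candidate windows of the same direction merge when the Pearson
correlation of their across-individual RD vectors is significant at
two-sided p < alpha under t = r·sqrt((n−2)/(1−r²)), df = n − 2.  Ties
at p = alpha do **not** merge (strict inequality); |r| = 1 is treated
as p = 0; a zero-variance vector makes the correlation undefined and
the pair never merges.  Merging is transitive left to right, which for
a chain of pairwise links is exactly the union-find of all passing
adjacent pairs (the property the test suite checks against a
brute-force oracle).

Calls merge into CNVRs when the gap between them (0 if touching or
overlapping) is below 20% of their combined length **and** their
per-individual mean-RD vectors correlate at p < 0.01.  This is a
pairwise fixpoint: after every merge all pairs are reconsidered with
the merged region's RD recomputed over its member windows, until no
pair qualifies — iterating to convergence is what makes the result
independent of input order.  A CNVR is typed GAIN or LOSS when all
constituent calls agree, otherwise BOTH; BOTH is reported as its own
class rather than forced into either column.

Cross-population CNVR identity uses ≥ 1 bp overlap; no
reciprocal-overlap fraction is required by default (none is published
for this workflow), but `min_reciprocal` exposes one for sensitivity
analysis.  Venn counts are connected components of the overlap graph,
so they are permutation-invariant and sum to the union count by
construction.

## Annotation stages

Genic context uses exon > intron > intergenic precedence, so the three
classes partition any region set.  Gene assignment keeps a gene when
the overlap covers ≥ 50% of the *shorter* feature — the denominator
choice makes complete containment of either feature always qualify,
matching the intent of "completely or partially overlapping".  Term
enrichment is the upper-tail hypergeometric test against a
user-supplied gene→term map (background defaults to all mapped genes)
with Benjamini–Hochberg FDR across terms; no live ontology database is
consulted.  QTL and cross-study intersections use ≥ 1 bp overlap on
half-open coordinates, and cross-study percentages are reported to two
decimals of the comparison set's size.

## Vst

`vst()` implements
`(Vtotal − (Vpop1·Npop1 + Vpop2·Npop2)/Ntotal)/Vtotal` with **unbiased
sample variances (divisor n − 1)** for all three terms.  The divisor
convention is not derivable from the formula as printed and changes
the numbers (the worked decomposition in the test suite gives 0.2222
under n − 1 and would give 0.3333 under n), so it is fixed here and
stated.  Per-individual values are mean normalized RD over the
region's windows — the resequencing analogue of the SNP-array log-R
ratio the statistic was originally defined on; a `log2(RD)` option is
provided for comparison (with a floor of 0.01 before the log, so
homozygous deletions stay finite).  When Vtotal = 0 the statistic is
undefined: the record is flagged and excluded from means and rankings
rather than set to 0.  Negative values (within-variance above pooled)
are reported unclamped.  "Significant divergence" has no analytic test
in this workflow; selection is rank-based and both conventions in use
— top 5 regions and the top 1% — are emitted.  Permutation-based
significance would be a natural extension but is out of scope.

## qPCR validation

`ddct_copy_number()` averages technical replicates (mean Ct), forms
ΔCt = Ct_target − Ct_reference, ΔΔCt against an explicit calibrator
sample, and scales `2^−ΔΔCt` by the calibrator's copy number (2).
Perfect amplification efficiency is assumed, as the 2^−ΔΔCt method
does.  Concordance against sequencing states classifies estimates at
the integer midpoints 1.5 / 2.5.

## What the simulator emulates — and what it does not

`simulate_populations()` + `simulate_depth()` reproduce the design of a
three-ecotype resequencing panel: 3 × 8 individuals, ~7× mean depth,
800-bp windows, an L-shaped region-size distribution (truncated
geometric over 1–10 windows, ~88% at 1–2 windows), duplications
outnumbering deletions 3:1, shared and population-specific regions with
carrier frequencies 0.25–0.9, and a few divergent regions fixed in one
population.  Carriers receive integer copy numbers (LOSS 0/1, GAIN
3/4, 30% homozygous); planted boundaries snap to the window grid so
truth comparisons are exact.

Depth noise models the *aggregated base count* of a window:
`X ~ Poisson(mean_depth · window_size · cn/2)`, depth `X/window_size`.
At 7× and 800 bp this gives a coefficient of variation of ~1.3% — the
clean, well-mapped-genome case.  Real panels are overdispersed by
mappability, GC and batch structure; the negative-binomial mode
(`Var = μ + φμ²`, default φ = 0.1, CV ≈ 32%) is the stress case, under
which the default thresholds lose heterozygous events — passing tests
under Poisson noise therefore demonstrate correctness of the machinery,
not robustness to every real-data artifact.  The simulator also does
not model reference errors, segmental duplications or partial-window
CNV boundaries.  A deterministic mode (`noise = "none"`) returns
expectations exactly and is used for exact-value tests.

## Problem sizes and determinism

The test suite and the acceptance script run: recovery on 3 chromosomes
× 2.4 Mb (9,000 windows) × 24 individuals with 41 planted regions of
≥ 4 windows; a 10,000-window null panel for specificity; and 100
replicates of a 16-individual fixed-difference panel for Vst recovery —
sizes chosen so each stage is exercised at realistic per-window
statistics while a full run stays interactive.  All generators take
explicit seeds and restore the caller's RNG state, so identical seeds
give byte-identical artifacts.

## Known limitations

* Integer copy-number genotyping per individual is out of scope; the
  caller reports GAIN/LOSS/NORMAL states and mean RD only.
* Depth must be precomputed per window; BAM ingestion is not part of
  the supported contract.
* The empirical 0.65/1.35 cutoffs assume ~diploid autosomes; haploid
  sex chromosomes in heterogametic individuals need the per-chromosome
  normalization mode and interpretation care.
* Enrichment assumes the supplied term map is complete for the
  background; no gene-length or linkage bias correction is applied.
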