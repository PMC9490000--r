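# rdcnv

Copy number variants (CNVs) — genomic segments present in more or fewer
than the diploid two copies — are a major source of structural variation
and of phenotypic differences between livestock populations.  `rdcnv`
implements the read-depth workflow used to characterise CNVs in
multi-population whole-genome resequencing panels (e.g. three sheep
ecotypes at ~7× coverage): it detects CNV windows per individual,
aggregates them into population-level CNV regions (CNVRs), accounts for
shared and population-specific regions, annotates them, scans
population pairs for divergent copy number, and validates calls against
qPCR — plus a simulator that generates whole panels with planted CNVs
so every stage can be verified against a known truth set.

## The method

The genome is tiled into fixed windows (default 800 bp).  Each
individual's per-window depth is divided by that individual's median, so
normalized read depth (RD) has a diploid baseline of 1.0 — a
heterozygous deletion sits near 0.5, a single-copy duplication near
1.5.  A window is a CNV window for an individual only when **both** of:

* statistical criterion: RD < 1 − 2·STDEV (deletion) or
  RD > 1 + 2·STDEV (duplication), with STDEV the individual's standard
  deviation of normalized RD;
* empirical criterion: RD < 0.65 (deletion) or RD > 1.35 (duplication).

Windows are kept at the population level when carrier frequency ≥ 0.05
or at least 3 carriers are homozygous (RD < 0.25 or > 1.75).  Adjacent
candidate windows merge into a call when the Pearson correlation of
their across-individual RD vectors is significant at p < 0.05
(Student's t, df = n − 2); calls merge into CNVRs when the gap between
them is under 20% of their combined length and their RD vectors
correlate at p < 0.01.  Population differentiation per CNVR is

```
Vst = (Vtotal − (Vpop1·Npop1 + Vpop2·Npop2)/Ntotal) / Vtotal
```

computed on per-individual mean RD over the region (1 = fixed
difference, ≈0 = no structure).  qPCR copy number is estimated as
`2 × 2^−ΔΔCt` against a diploid calibrator.

## Worked example

Simulate a 3-population × 8-individual panel at 7× with planted CNVRs
(shared, population-specific and two fixed differences), then run the
full pipeline:

```r
library(rdcnv)

genome <- genome_layout(paste0("chr", 1:2), c(1.6e6, 1.2e6))
grid   <- make_window_grid(genome, 800)
truth  <- simulate_populations(grid, n_shared = 12, n_unique = 4,
                               n_divergent = 2, seed = 42)
raw    <- simulate_depth(truth, mean_depth = 7, noise = "poisson", seed = 43)

res    <- run_cnv_pipeline(raw, truth$popmap)
report <- make_summary_report(res, genome)

report$events
#>   population n_events n_gain n_loss total_length_mb mean_length_kb
#> 1       pop1       86     67     19            0.08           0.99
#> 2       pop2       94     73     21            0.10           1.04
#> 3       pop3       69     45     24            0.07           0.95

report$venn
#>      populations  n
#> 1           pop1  7
#> 2 pop1&pop2&pop3 12
#> 3           pop2  7
#> 4           pop3  4

report$vst
#>           pair  mean_vst   top_vst top_cnvr
#> 1 pop1_vs_pop2 0.2553141 0.9991684 ucnvr_13
#> 2 pop1_vs_pop3 0.1457827 0.9989321  ucnvr_4
#> 3 pop2_vs_pop3 0.1825452 0.9991203 ucnvr_11

recovery_stats(res$union_cnvrs, truth)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1
```

Per-population event counts split into gains and losses with their mean
lengths; the Venn table shows the 12 planted shared CNVRs recovered as
shared plus the population-specific ones; the two planted fixed
differences top the Vst rankings at ≈1; and every planted region is
recovered with no false positives at this noise level.  With
`output_dir =` the pipeline also writes the per-region TSV artifacts
and a JSON summary.

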