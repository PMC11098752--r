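# dpcrepair

Quantification of transcription-coupled DNA–protein crosslink (DPC) repair
from genome-binned sequencing counts.

Formaldehyde traps proteins covalently on DNA; cells remove these DPCs
preferentially from transcribed regions (transcription-coupled DPC repair,
initiated by Pol II stalling and the CSB/CSA machinery). A DPC-enrichment
sequencing assay read out directly after a formaldehyde pulse (0 h) and
after recovery (4 h) quantifies this as per-bin signal loss. This package
implements the complete computational chain for that assay, for anyone
analysing binned DPC-seq / nascent RNA-seq data or validating such a
pipeline on simulated data:

* **Binning and counting** — 1-kb genome partition; featureCounts-style
  fragment aggregation (unstranded, MAPQ ≥ 30, primary-only, duplicate-free,
  fractional 1/n assignment of bin-straddling fragments); replicate
  combining on a common library scale; per-bin TPM.
* **Filtering and normalization** — IQR outlier removal
  (Q1 − 1.5·IQR / Q3 + 1.5·IQR, no low-end removals when the bound is
  negative), DNA TPM floor (0.08), union propagation of removals across all
  datasets, and rescaling of the 0 h sample to the 4 h level on
  zero-transcription reference bins (bins with zero nascent-RNA reads).
* **Repair statistics** — per-bin repair percent
  `100 × (c0h − c4h)/c0h`, median/Q1/Q3 summaries over expressed bins
  (> 3 TPM), expression-stratified summaries, 5′→3′ gene-level repair
  profiles, and unpaired two-tailed t-test group comparisons.
* **FRAP** — background correction, pre-bleach normalization, and the
  immobile fraction
  `1 − (I_rec,treated − ⟨I_bleach⟩)/(⟨I_rec,NT⟩ − ⟨I_bleach⟩)` over
  configurable late recovery windows (built-in profiles: frames 414–450 and
  16–30 of the post-bleach series).
* **qPCR** — relative DPC levels by the 2^−ΔΔCt chain (DPC vs free DNA, vs
  untreated, vs FA 0 h) and nascent-transcription time courses by 2^−ΔCt.
* **Synthetic data** — a seeded generator (genomes, expression tracks, DPC
  bin counts, FRAP traces, Ct tables) with exact ground truth, so every
  stage above is testable end to end without downloads.

## Worked example

```r
library(dpcrepair)

cfg <- simulation_config(seed = 1)        # 50 Mb genome, 50,000 1-kb bins,
                                          # true expressed-bin repair 0.5
ex  <- simulate_dpc_experiment(cfg, "WT")
res <- run_repair_pipeline(ex$t0, ex$t4, ex$expression, ex$bins)
res$summary
#>   label n_bins       q1  median       q3
#> 1 tpm>3  13884 43.96223 50.17258 55.60144
res$norm
#> <dpc_normalization> scale ratio 0.6329 over 35726 zero-transcription reference bins
```

The median expressed-bin repair of **50.2%** recovers the generator's true
repair fraction of 0.5 through the full chain (replicate combining, IQR +
TPM-floor filtering, zero-transcription normalization); the scale ratio of
0.63 is the library-size correction the normalization inferred. The same
pipeline on a transcription-blocked condition (`"THZ1"`, genotype factor 0)
returns a median of −0.06%: no preferential repair.

The numbered scripts under `analysis/` run the full narrative —
`01_simulate.R` writes fixtures (chrom.sizes, BED fragments, bedGraphs, FRAP
and Ct CSVs) under `results/sim/`, and `02`–`06` count, filter/normalize,
compute repair statistics, estimate the FRAP immobile fraction and evaluate
the qPCR chains, writing their tables under `results/`.

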