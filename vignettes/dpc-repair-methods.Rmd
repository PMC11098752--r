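---
title: "Quantifying transcription-coupled DPC repair from binned sequencing counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-coupled DPC repair from binned sequencing counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Formaldehyde and other aldehydes covalently trap proteins on DNA, forming
DNA–protein crosslinks (DPCs). Transcription-coupled DPC repair removes these
lesions preferentially from actively transcribed regions: a sequencing assay
that enriches DPC-associated DNA (DPC-seq) directly after a formaldehyde
pulse (0 h) and again after a recovery period (4 h) shows depletion of signal
at 4 h specifically in expressed regions, while non-transcribed regions are
left essentially untouched. `dpcrepair` implements the computational half of
that assay — everything downstream of alignment — together with the
FRAP immobile-fraction and qPCR quantifications that accompany it, and a
synthetic-data generator with exact ground truth so the whole chain is
testable without any sequencing download.

## The repair statistic and its normalization

The genome is partitioned into 1,000-base bins and each sample's aligned
fragments are aggregated per bin under featureCounts-style rules: unstranded,
template spans rather than individual mates, MAPQ ≥ 30, primary alignments
only, duplicates ignored, and a fragment overlapping $n$ bins contributing
$1/n$ to each (so totals are conserved exactly). Replicates are combined by
scaling each replicate to the mean of the replicate totals and averaging
bins.

Per bin the repair statistic is

$$\text{repair percent} = 100 \times \frac{c_{0h} - c_{4h}}{c_{0h}},$$

on *normalized* counts. The normalization uses zero-transcription reference
bins: bins whose nascent-RNA raw read count is exactly zero carry no
transcription-coupled repair, so their aggregate DPC signal should be equal
at both timepoints. The 0 h counts are therefore rescaled by
$\sum_\mathrm{ref} c_{4h} / \sum_\mathrm{ref} c_{0h}$, which simultaneously
absorbs library-size differences. Two consequences are worth stating:

* aggregate repair over the reference bins is *exactly* zero after scaling
  (a test asserts this to 1e-9 relative tolerance), and
* the statistic is invariant to any common positive rescaling of either
  sample's library.

Before normalization a filtering cascade runs on the replicate-combined DNA
tables: (1) IQR outlier removal — bins below $Q_1 - 1.5\,\mathrm{IQR}$ or
above $Q_3 + 1.5\,\mathrm{IQR}$; if the lower bound is negative no low-end
bins are removed; (2) a DNA TPM floor of 0.08 (strictly-below bins are
discarded — they offer little opportunity to observe repair); (3) a bin
removed by any rule in any dataset is removed from all datasets. For
plotting and statistics a final RNA TPM threshold removes bins with TPM less
than or equal to the threshold (default 3; with no threshold, zero-TPM bins).
Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7) everywhere; the convention is configurable and a
sort-based oracle in the test suite pins its behaviour.

Bins whose normalized 0 h count is zero are flagged invalid rather than
producing infinities; repair percentages are deliberately *not* clipped —
negative values (apparent net gain) are real features of count noise and
clipping them would bias medians upward.

## What the generator emulates

`simulation_config()` fixes the study conditions:

* **Genome**: 2 chromosomes × 25 Mb = 50,000 bins of 1 kb; 1,200
  non-overlapping genes of 8–20 kb placed uniformly at random, 20% silent.
  This yields ≳ 13,000 expressed bins — enough that the median expressed-bin
  repair estimate has sub-point Monte-Carlo error.
* **Expression**: expressed-gene TPMs are zero-inflated log-normal, rescaled
  so the per-bin true-TPM track sums to $10^6$ (proper TPM semantics); the
  measured track draws Poisson counts with mean `tpm × rna_depth / 1e6`
  (default depth $2\times10^7$, so a 3-TPM bin averages 60 reads and
  intergenic bins are exactly zero — the zero-read reference set is clean).
  A bin straddled by two distinct genes (a rare boundary event) carries the
  larger TPM.
* **DPC load**: the 0 h expectation is uniform across genic and intergenic
  bins (default 50 expected fragments per bin); the 4 h expectation is
  $1 - r(\mathrm{TPM}) \times g$ of it, where
  $r(t) = r_{\max}\, t / (t + K)$ is a saturating repair curve
  ($r(0) = 0$ always; $K = 0$ degenerates to a step of height $r_{\max}$ on
  expressed bins) and $g$ is a per-condition genotype factor
  (WT = 1; CSA-KO, CSB-KO and THZ1 = 0). Defaults are $r_{\max} = 0.5$,
  $K = 0$ — a flat 50% expressed-bin repair fraction; the monotonicity
  analyses use $r_{\max} = 0.8$, $K = 50$ TPM so the repair fraction varies
  across expression strata.
* **Noise**: Poisson by default; negative-binomial with configurable
  dispersion as an option. Each replicate × timepoint sample receives its own
  library-size factor drawn log-uniformly from $[0.5, 2]$, so the
  normalization stage always has real work to do.

Ground truth (per-bin true TPM and true repair fraction, plus the library
factors) is returned alongside the counts and equals
`repair_fraction(TPM) × genotype factor` exactly, by construction.

What the generator does **not** emulate: GC and mappability bias, alignment
artifacts, fragment-length structure within bins (counts are drawn at bin
level except for the small fixture-writing path), DNA–DNA crosslinks, or
replication-coupled lesion processing. Passing the recovery tests therefore
shows the *estimator chain* is correct and unbiased under the stated noise
model — not that real libraries are free of coverage bias.

One behaviour discovered with the saturating curve and kept: when the spread
of 4 h counts among expressed bins is narrow, the combined 4 h table's IQR
can be tight enough that $Q_1 - 1.5\,\mathrm{IQR} > 0$, and the low-end rule
then removes the most deeply repaired bins. The cascade applies the rule
literally; under the default flat-repair conditions the lower bound is
negative (no low-end removals), matching how the filter behaves on real
libraries. For stratified analyses the stratum edges are taken as quartiles
of the surviving expressed-bin TPM rather than fixed values, so all strata
stay populated however the filters trim the tails.

## FRAP immobile fraction

Traces are background-corrected (strip outside the nucleus) and divided by
the mean pre-bleach intensity, so the pre-bleach plateau is 1. With
$I_\mathrm{rec,FA}$ the mean RFI over a late recovery window (per treated
cell, then averaged), $\langle I_\mathrm{rec,NT}\rangle$ the same over
untreated cells, and $\langle I_\mathrm{bleach}\rangle$ the cohort mean of
the first post-bleach measurement,

$$\text{immobile fraction} = 1 - \frac{I_\mathrm{rec,FA} - \langle I_\mathrm{bleach}\rangle}{\langle I_\mathrm{rec,NT}\rangle - \langle I_\mathrm{bleach}\rangle}.$$

The identities at the endpoints (0 when treated recovery equals the
untreated level, 1 when it sits at the bleach level) hold for any window.
Window frames are 1-based indices into the post-bleach recovery series —
under that reading both published windows (414–450 of a 450-frame recovery;
16–30 of a 30-frame recovery) end exactly at the last acquired frame, which
is why that interpretation was adopted. The bleach reference pools treated
and untreated cells by default; per-arm referencing is exposed as an option
since the cohort definition is a genuine free choice. The simulator's
mono-exponential recovery toward $1 - f(1 - b)$ (bleach floor $b$) makes the
estimator exactly consistent: with a plateaued window the cohort estimate
equals $f$ analytically, and a plateau check warns when the untreated mean
still rises across the window.

## qPCR chains

Relative DPC levels follow the $2^{-\Delta\Delta C_t}$ chain: DPC-associated
DNA vs free DNA within each sample, then vs the untreated sample, then all
levels divided by the FA 0 h value (so FA 0 h ≡ 1 exactly). Nascent
transcription time courses follow $2^{-\Delta C_t}$ against each treatment
arm's 0 min sample. Replicate Cts are averaged on the Ct scale before
exponentiation (standard practice) and amplification efficiency is fixed at
2. Both chains are invariant to adding a constant to every Ct — a property
test exercises this on random tables.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) everywhere; bin widths
  divide chromosomes with one truncated terminal bin, which TPM computation
  length-corrects.
* The MAPQ filter is ≥ 30; fractional counting is $1/n$ per overlapped bin
  (the named tool's documented `--fraction` semantics), not
  overlap-length-proportional.
* `combine_replicates` is permutation-invariant; tables with zero totals are
  rejected rather than silently propagated.
* The two-group comparison defaults to the equal-variance Student t-test
  (Welch exposed via `welch = TRUE`), two-sided.
* Degenerate inputs error early and explicitly: fewer than 4 bins for IQR
  filtering, an empty zero-transcription reference, a non-positive pre-bleach
  mean, a missing qPCR reference sample.

## Problem sizes

The packaged analyses and tests run the full 50,000-bin genome for the
headline recovery checks (median expressed-bin repair within 3 points of the
true 50%, null conditions within 2 points of 0) and smaller 4,000-bin
genomes for unit-level properties; counting and IQR behaviour is pinned
against brute-force oracles on hundreds of randomized small instances. FRAP
cohorts use 30 cells per arm at RFI noise sd 0.05, matching the scale of a
typical live-imaging experiment.

## Known limitations

Fragment counting consumes template spans; mate pairs split across bins are
the caller's responsibility to merge. The IQR filter is applied to DNA
tables only (removals propagate to RNA), and the zero-read RNA reference is
selected after mask propagation; computing it before propagation is the
plausible alternative and changes reference membership only through the
DNA-side masks. No smoothing is applied to gene-level profiles. Blacklist
regions, alternative normalizations (quantile, median-of-ratios) and
efficiency-corrected qPCR are out of scope.
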