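---
title: "Genomic instability assessment from shallow WGS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic instability assessment from shallow WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdgia)
```

## The problem

High-grade serous ovarian cancers deficient in homologous recombination
repair (HRD) respond to PARP inhibition, so HRD status guides therapy.
Commercial genomic-instability assays are expensive and logistically
constrained; an academic alternative scores instability directly from
shallow whole-genome sequencing (sWGS, 0.4–0.8× effective coverage) of FFPE
tumor DNA. At that depth point mutations are invisible but copy number is
not: read counts in genomic windows track the tumor's copy-number profile.

`hrdgia` implements this scoring end to end. The scored unit is the
**large-scale genomic alteration (LGA)**: a copy-number breakpoint between
two adjacent segments on the *same chromosome arm*, both at least 10 Mb
long, whose mean log2 copy ratios differ by at least a step threshold.
Centromeres never contribute breakpoints. HRD genomes accumulate such
arm-scale scars; their count is the instability readout.

## Pipeline model

### Binning and normalization

Each chromosome arm is tiled left-to-right with non-overlapping windows
(the published description says "sliding windows" but reports a single LGA
count per window model; non-overlapping tiling is the standard shallow-WGS
reading and keeps counts well defined — we treat this as an explicit open
question resolved by design). Six window models spanning 5–1000 kb are used
by default: 5, 25, 50, 100, 500 and 1000 kb.

Per window model, raw counts are cleaned and normalized
(`normalize_counts()`):

* bins with zero count, or GC fraction outside [0.28, 0.72], are masked
  with a reason code;
* if more than 50% of bins are masked the sample fails QC and is reported
  **ND** (undetermined) rather than given a score — mirroring how a
  degraded-DNA sample must be reported in practice;
* GC bias is corrected by dividing each count by the median count of its GC
  decile (deciles over retained bins). The correction is applied only when
  the retained GC values span enough dynamic range (interquartile range at
  least 0.05, at least 500 bins): over a narrower range the GC effect is
  below count noise, and decile medians computed on a few dozen bins of a
  multimodal copy-number mixture would inject noise instead of removing
  bias. This matters at coarse windows, where per-bin GC averages toward
  0.5;
* counts are converted to log2 ratios by subtracting the median of
  `log2(count)` over retained bins, so the median retained log2 ratio is
  exactly zero (equivalently, division by the median count whenever the
  median is attained). Ratios are invariant to global scaling of counts,
  i.e. to sequencing depth.

### Segmentation

Each arm's retained log2 ratios are segmented by exact penalized least
squares (`segment_arm()`): minimize

$$\sum_k \mathrm{SSE}(\text{segment}_k) \;+\; \beta\,(\#\text{segments}-1),
\qquad \beta = c\,\hat\sigma^2 \log n,$$

with `penalty_scale` $c = 3$ and $\hat\sigma$ the median-absolute-deviation
of successive differences divided by $\sqrt2$ (the standard robust
estimator of per-bin noise, insensitive to true copy steps). The optimum is
found by PELT, which prunes candidates without losing exactness for this
cost; the test-suite verifies exact agreement with an $O(n^2)$ dynamic
program on hundreds of random profiles. $\beta$ is floored at a tiny
positive value so noiseless profiles resolve to the fewest segments.
$c = 3$ exceeds the $2\sigma^2\log n$ scale of the largest spurious
noise reduction, which is why flat arms stay whole.

Two merge passes follow (`merge_segments()`):

1. **Transition-bin absorption.** The bin straddling a true breakpoint
   averages the two flanking levels and tends to come out as its own 1-bin
   segment at coarse windows, which would hide the flank adjacency from the
   LGA rule. Segments with fewer than `min_seg_bins = 3` bins are absorbed
   into the neighbor with the closer mean.
2. **Threshold merging.** While any adjacent pair differs by less than
   `merge_threshold = 0.10`, the closest pair is merged (leftmost on ties,
   for determinism), with bin-count-weighted means.

### LGA counting and integration

`count_lga()` applies the definitional rule: both flanks ≥ `min_lga_len`
(10 Mb, the scale that makes an alteration "large") and an absolute mean
step ≥ `delta = 0.25`. A one-copy change in a diploid tumor at purity $p$
shifts the observed ratio by a factor $(p\,r_2 + 1-p)/(p\,r_1 + 1-p)$;
$\delta = 0.25$ keeps one-copy events detectable down to roughly 40%
purity, the lower end of usable FFPE purity. Raising `delta` can only
decrease the count (tested as a monotonicity property), and the count is
invariant to global ratio shifts, so it does not depend on where the median
sits.

The per-model counts are integrated into the **GIA score** as their median,
half-integers rounded up (`integrate_models()`). The original pipeline
feeds its window models into a neural-network integrator whose
architecture, training data and weights are not published; a rounded median
is deterministic, robust to one or two divergent window models, and fully
auditable, so we adopt it as the integration rule. If any window model
fails QC the sample is ND and no score is emitted.

### Classification

Three-class calling: HRN for GIA ≤ 14, HRM for 15–19, HRD for ≥ 20.
The published inequalities leave 14, 15, 19 and 20 formally unassigned
("15 < LGA < 19"); we close the bands as above so every integer has a
class, consistent with the "GIA 15–19" range used in the published
band-mapping table. Two-class calling collapses HRM into the positive
group (positive iff GIA ≥ 15). Reference (Myriad-style) scores are banded
N ≤ 42 / M 43–55 / D ≥ 56, with clinical positivity at ≥ 42; a score of
exactly 42 is banded N *and* positive — the two published rules genuinely
overlap there and we surface both facts rather than silently reconciling
them (no validation-cohort sample sits at 42).

## Concordance statistics

`cohens_kappa()` computes $\kappa = (p_o - p_e)/(1 - p_e)$ with the
standard agreement bands (< 0 none, ≤ 0.20 slight, ≤ 0.40 fair, ≤ 0.60
moderate, ≤ 0.80 substantial, ≤ 1 almost perfect). Its p-value uses the
large-sample normal approximation under independence; on a 20-sample table
this is approximate, and we treat printed p-values as non-reproducible
(the producing software's method is unstated). `ppa()` is the
both-positive count over reference-positive count. `spearman_rho()` is the
Pearson correlation of average ranks with a t-approximate p-value.
`fisher_exact()` uses the two-sided "probability ≤ observed" convention
(delegated to `stats::fisher.test`, which implements exactly that; the
test-suite cross-checks it against full hypergeometric enumeration).

Undetermined (ND) samples are always excluded from contingency analyses
and the exclusion is counted and reported. One published inconsistency is
worth flagging: the validation text reports 16 R-positive samples while
the corresponding table's rows sum to 17; the package always reports
counts derived from the tables.

## Survival analysis

Kaplan–Meier estimation, the k-group log-rank test and univariate Cox
regression stand on the `survival` package (`survfit`, `survdiff`,
`coxph` with Breslow tie handling). "Mean PFS" is implemented as the KM
**restricted mean**, the area under the step curve up to the largest
observed time — the published analysis does not state which mean it used,
and this choice changes the number, so it is worth stating prominently.
With no censoring the restricted mean equals the arithmetic mean of the
times. Days are converted to months at 30.4375 days/month. Complete
separation in the Cox model is flagged rather than estimated.

## The synthetic-data generator

No patient data accompany the published study ("dataset cannot be
shared"), so the package ships a generator that makes every stage testable:

* **Truth profiles** (`simulate_truth_profile()`): piecewise-constant copy
  ratios on the arm grid, levels drawn from {0.5, 1.0, 1.6, 2.4} relative
  to diploid, every LGA flank ≥ 10 Mb, consecutive levels always ≥ 0.5
  apart in linear ratio. The level set is chosen so that at the lowest
  studied purity (0.4) every truth step still exceeds the detection
  threshold after dilution — the generator emits alterations of the
  magnitude the assay is designed to see. Short (3–8 Mb) "distractor"
  segments are inserted inside long segments with same-level flanks: their
  breakpoints never satisfy the LGA rule, and a segmentation that misses
  them merges identical levels, so they can never create a spurious LGA.
  The requested LGA count is verified by an independent brute-force
  recount before the profile is returned.
* **Bin counts** (`simulate_bin_counts()`): expected count
  $\mu = \text{coverage}\times\text{width}\times(p\,r + 1-p)\times
  b(\mathrm{gc})$, negative-binomial noise with size 100 (per-bin log2
  noise ≈ 0.15 at sWGS depths, the overdispersion scale reported for FFPE
  sWGS bins), and a smooth unimodal GC bias bump $b$ of amplitude 0.3
  peaking at GC 0.5. Per-bin GC is short-range variation (iid around 0.5,
  sd 0.06, clamped to [0.30, 0.70]) — deliberately *not* a long-period
  positional wave, which would correlate GC with copy-number segments and
  defeat any median-based GC correction in a way real genomes do not.
* **Cohorts** (`simulate_cohort()`): class proportions ~ (0.65, 0.20,
  0.15) for HRD/HRM/HRN (the validation cohort's 13/4/2 composition), GIA
  and reference scores drawn inside their class-consistent bands (HRN
  reference scores avoid exactly 42, the ambiguous edge), and exponential
  PFS with class means 2893/1217/631 days — the published 95.04 / 39.97 /
  20.73 month means at 30.4375 days/month. Exponential is the simplest
  model reproducing the published ordering without inventing shapes the
  study does not state. Censoring is Bernoulli at 20% by default.

The default reduced karyotype (6 chromosomes, 12 arms, 600 Mb) preserves
arm-scale structure at a tenth of genome size for speed; the full hg19 arm
table is packaged for real-data use (`hg19_genome()`).

### What passing tests do and do not show

The simulator's parameters are stand-ins for study conditions, not
estimates of the study's data: the published work states coverage
(0.4–0.8×) and the clinical summaries, but no noise model, purity values
or per-patient survival times. Passing the recovery property shows the
pipeline correctly counts arm-scale alterations under realistic
overdispersion, GC bias, purity dilution and window aggregation. It does
not show robustness to FFPE artifacts beyond overdispersion, mappability
and blacklist issues, replication-timing waves, subclonal heterogeneity,
or real GC chemistry — none of which the generator emulates.

A power observation worth making explicit: with 20-patient cohorts (the
published cohort size) and exponential PFS at the published class means,
simulated cohorts frequently fail to reproduce the strict restricted-mean
ordering HRD > HRM > HRN — the HRM and HRN groups hold only a few patients
each. The test-suite therefore checks the ordering property on larger
simulated cohorts (n = 400), where sampling noise no longer dominates; the
default cohort size stays at 20 because it *is* the study condition.

## Numerical choices and degenerate inputs

* Penalized-SSE minimization is exact (PELT ≡ optimal partitioning);
  ties in the DP argmin resolve to the earliest candidate, and
  smallest-gap merging breaks ties leftmost — both for determinism.
* $\beta$ floored at $10^{-12}$ so zero-noise arms segment minimally.
* Arms with fewer than 2 retained bins return a single flagged segment.
* GIA median uses round-half-up (`floor(m + 0.5)`).
* All simulator entry points take an explicit integer seed and restore the
  caller's RNG state; identical inputs and seed give byte-identical
  outputs.
* Degenerate statistics raise explicit errors rather than NaN: kappa on a
  single-category table, PPA with no reference positives, Spearman on a
  constant vector, log-rank with one group.

## Problem sizes used by the checks

The test-suite segments ~240 random arm profiles against the exact-DP
oracle (n ≤ 50 bins each), scores 100 simulated samples end-to-end at 5 kb
base resolution with all six window models (the recovery property), sweeps
~300 random 2×2 tables against the Fisher enumeration oracle, and runs the
survival property suites at up to 1000 subjects. The acceptance script
re-scores 40 simulated samples and one 400-patient synthetic cohort.
These sizes are the package's own choice of a thorough-but-quick default;
all of them are parameters, not limits.

## Known limitations

* The integration rule (median) and all segmentation constants are
  declared substitutes for unpublished internals of the original pipeline,
  not reconstructions; they are exposed in `lga_params()` and logged per
  run precisely because they are not published constants.
* Absolute copy-number calling, ploidy/purity estimation and the
  commercial score's components (LOH, TAI, LST) are out of scope; the
  reference score is consumed as a given number.
* BAM handling is out of scope for the core: the pipeline consumes binned
  count tables (any standard binner can produce them).
* Printed p-values and Spearman coefficients of the validation study
  require its unpublished raw scores and are deliberately not reproduction
  targets; the statistics themselves are validated against oracles and
  reference implementations instead.
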