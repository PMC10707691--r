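# hrdgia

Homologous recombination deficiency (HRD) scoring from shallow
whole-genome sequencing (sWGS), for labs and methodologists who want an
auditable, fully testable academic alternative to commercial
genomic-instability assays.

At 0.4–0.8× coverage, binned read counts track a tumor's copy-number
profile. `hrdgia` normalizes per-window counts to log2 copy ratios (with
GC correction and QC masking), segments each chromosome arm by exact
penalized least squares (PELT), and counts **large-scale genomic
alterations (LGAs)** — breakpoints between adjacent same-arm segments,
both flanks ≥ 10 Mb, with a log2-ratio step ≥ δ:

```
LGA(arm) = #{ i : len(S_i) ≥ 10 Mb, len(S_i+1) ≥ 10 Mb, |mean(S_i+1) − mean(S_i)| ≥ δ }
```

LGAs are counted in six window models (5–1000 kb) and integrated into the
**GIA score** (genomic instability assessment) as the rounded median of
the per-model counts. Classification: HRN (negative) for GIA ≤ 14, HRM
(mild) for 15–19, HRD (deficient) for ≥ 20; two-class positivity at
GIA ≥ 15. The package also provides method-concordance statistics
(Cohen's κ with agreement bands, percent positive agreement, Spearman's ρ,
Fisher's exact test), Kaplan–Meier / log-rank / Cox survival analysis by
HRD class, and a seeded simulator of FFPE tumor sWGS bin counts and
clinical cohorts so every stage is testable without external data.

See `vignettes/gia-methods.Rmd` for the model, parameter rationale and
design decisions.

## Worked example

Simulate a tumor with 18 true LGAs at ~54% purity, score it, classify it:

```r
library(hrdgia)
g   <- reduced_genome()                       # 6-chromosome 600 Mb test karyotype
cfg <- sim_config(seed = 11)
tp  <- simulate_truth_profile(g, 18, seed = 11, config = cfg)
bins <- simulate_bin_counts(tp, g, 25000, cfg)
res <- gia_score(bins, g, windows = c(25, 50, 100, 500, 1000) * 1000)
res
#> GIA result [OK]
#>   per-model LGA: 25000=16 50000=18 1e+05=18 5e+05=18 1e+06=18
#>   GIA = 18
classify_three(res$gia)
#> [1] "HRM"
```

Five window models agree on 18 (the 25 kb model reads 16); the integrated
GIA of 18 recovers the simulated truth exactly and lands in the HRM
("mild") band — one alteration short of the HRD class at ≥ 20.

Concordance on the packaged 20-patient validation cohort:

```r
tabs <- validation_tables()
cohens_kappa(tabs$r_vs_w)       # two sWGS chemistries, 3 classes
#> Cohen's kappa = 0.736 (substantial), p = 3e-06, n = 20
ppa(tabs$r_vs_myriad)           # chemistry R vs reference assay
#> PPA = 16/17 = 94%
```

Survival by HRD class on a synthetic cohort (restricted-mean PFS, months):

```r
co <- simulate_cohort(400, sim_config(seed = 11))
survival_by_class(co)$by_class
#>   class   n events rmean_days rmean_months median_days
#> 1   HRD 271    231   3304.794    108.57638      2319.2
#> 2   HRM  82     67   1505.733     49.46966      1177.8
#> 3   HRN  47     32    774.585     25.44838       532.1
```

The class ordering (HRD longest PFS under PARP-inhibitor-era treatment,
HRN shortest) mirrors the clinical finding the score is meant to carry.

A thin command-line wrapper with `simulate` / `score` / `compare` /
`survival` subcommands is installed at
`system.file("cli", "hrdgia.R", package = "hrdgia")`.

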