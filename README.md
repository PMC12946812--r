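# rtaccum

Delivered-dose analysis for fractionated pelvic radiotherapy: how much does
day-to-day **bowel-cavity (BC) gas motion** shift the dose a rectal-cancer
patient actually receives away from the approved plan, and what does that
mean for acute bowel toxicity risk?

`rtaccum` is aimed at radiotherapy physicists and methodologists who want a
fully inspectable, reproducible implementation of a daily-recalculation /
dose-accumulation workflow:

* **synthetic pelvic cohorts** — analytic phantoms (body, ~1170 cc PTV,
  bladder, rectum, bone, whole bowel with gas pockets) realising a
  28-patient x 25-fraction course (50 Gy / 25 fx) with *controlled*
  per-fraction BC volume change and a known ground-truth deformation field;
* **HU → relative electron density** — a three-segment calibration (air /
  soft tissue / bone, factors 0.995 / 0.977 / 0.972) with factor derivation
  from paired dose sets;
* **a density-aware dose engine** — a transparent exponential-attenuation,
  12-beam coplanar model whose job is to make gas perturb dose in the
  physically correct direction (it deliberately is not a clinical dose
  algorithm);
* **QA-gated deformable accumulation** — pull-back dose warping, landmark
  TRE ≤ 3 mm and gamma 2%/2 mm ≥ 90% gates, voxel-wise summation over the
  course;
* **DVH endpoint calculus** — PTV D2%/D50%/D98%, whole-bowel
  D0.03cc/D150cc, V45; absolute (Δ, Gy) and relative (δ, %) deviations
  `δ = (D_delivered − D_plan) / D_plan × 100`;
* **association statistics** — Spearman ρ with BCa bootstrap CIs, OLS
  slopes in Gy per 10% BC expansion with HC3 intervals, patient
  fixed-effects panel models with cluster-robust errors, and
  Benjamini–Hochberg correction over the five-endpoint family;
* **NTCP** — the logistic whole-bowel model
  `NTCP = 1 / (1 + (V50/V45)^k)` with V50 = 130 cc, k = 1.1, triage bands
  at 300/500 cc, and planned-versus-accumulated comparison.

The methods vignette (`vignettes/delivered-dose-methods.Rmd`) documents
every model, default and numerical choice.

## Worked example

The NTCP model evaluated at stratum-mean whole-bowel V45 values
(cc → probability of ≥ grade-2 acute bowel toxicity):

```r
library(rtaccum)
ntcp(c(352.21, 423.61, 460.82, 575.93))
#> [1] 0.7495779 0.7857351 0.8009146 0.8371668
```

i.e. 0.75 / 0.79 / 0.80 / 0.84 at two decimals — the risk increment from
planned to accumulated dose in the higher-V45 strata is about +0.04.

A small end-to-end course (4 patients, 3 fractions, 50 Gy course total so
V45/NTCP stay on their clinical scale; ~3 min on one core):

```r
cfg <- run_config(
  cohort = cohort_config(n_patients = 4, n_fractions = 3,
                         dvbc_mean_range = c(0, 50), seed = 7),
  prescription_gy = 50 / 3,
  n_boot = 500)
res <- run_course(cfg)

res$accumulated_summary$summary[, c("endpoint", "median_delta", "median_delta_pct")]
#>   endpoint median_delta median_delta_pct
#> 1       D2       0.0106           0.0203
#> 2      D50       0.0525           0.1049
#> 3      D98       0.0304           0.0720
#> 4  D0.03cc       0.6500           1.2451
#> 5   D150cc      -0.1446          -0.3379

res$ntcp_comparison
#> <ntcp_comparison> V50 = 130 cc, k = 1.1
#>   stratum n v45_planned_mean ... ntcp_planned_mean ntcp_accum_mean  p_ntcp
#> 1  grade1 4              113 ...             0.461           0.458  0.0319
```

The pattern to read off: the whole-bowel hotspot (D0.03cc) moves by an
order of magnitude more than near-minimum PTV coverage (D98) when bowel
gas varies — accumulated dose differs from planned dose selectively in the
high-dose tail.  `res$assoc_table` additionally reports, per endpoint,
Spearman ρ, the OLS slope per 10% BC expansion with raw and FDR-adjusted
p-values, and the within-patient fixed-effects slope; `res$qa_ledger`
records TRE, gamma pass rate and accept/exclude status for every fraction.

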