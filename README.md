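# lymphoti

Quantitative analysis of lymphoscintigraphy and limb volumetry for lower
extremity lymphedema (LEL), aimed at researchers studying whether preoperative
lymphatic imaging predicts the outcome of lymphovenous anastomosis (LVA).

Lymphoscintigraphy is read qualitatively: transport kinetics (K), dermal
backflow (D), time to first appearance of the ilio-inguinal nodes (T, minutes),
node visualization (N) and main-vessel visualization (V) are each graded on
the ordinal scale {0, 3, 5, 9} (collateral flow C is recorded but not scored).
These combine into the **transport index**

```
TI = K + D + 0.04·T + N + V,        TI ∈ [0.6, 45]
```

where non-visualized nodes score 9 on the time term, and the time term is
capped at 9 so that no appearance time scores worse than non-visualization.
The package computes TI both for the full 240-minute acquisition (TI240) and
for a censored 120-minute window (TI120) that uses only the 15-, 60- and
120-minute images: node times on omitted frames snap forward to the next
retained image, and nodes first seen after 120 minutes are re-scored as not
visualized.

Limb volume is summarized by the **lower extremity lymphedema index**

```
LELI = (Σᵢ cᵢ²) / BMI     (five circumference sites, cm; BMI in kg/m²)
```

and outcomes by the percentage change `%ΔLELI = 100·(pre − post)/pre`
(positive = volume reduction) at 1, 3 and 6 months after surgery.

The package provides:

- `transport_index()`, `censor_reads()`, `score_reads()`, `binarize_reads()`,
  `enumerate_reads()` — ordinal scoring, window censoring, binary criteria;
- `leli()`, `pct_delta_leli()`, `leli_excess()` — volumetry;
- `spearman_test()`, `mann_whitney_test()`, `wilcoxon_signed_rank_test()`,
  `kruskal_wallis_test()`, `icc_intrarater()` — the nonparametric battery,
  exact by enumeration in small samples (valid under ties) and tie-corrected
  asymptotic otherwise;
- `cohort_config()`, `calibrate_link()`, `generate_cohort()` — a synthetic
  45-patient cohort generator (Gaussian-copula ordinal reads driven by a
  latent severity, outcome model calibrated to a target TI-outcome rank
  correlation);
- `load_cohort()`, `run_study()`, `write_report()` — the end-to-end pipeline
  from CSVs to a structured report, plus a thin CLI in `inst/cli/lymphoti.R`.

## Worked example

```r
library(lymphoti)

# a single limb: mild kinetic delay, no dermal backflow,
# nodes mildly visible from the 60-min image
transport_index(K = 3, D = 0, node_time_min = 60, N = 3, V = 0)
#> [1] 8.4

# calibrate the generator's outcome slopes, simulate a cohort, run the study
cfg    <- calibrate_config(cohort_config(), n_cal = 1e5, seed = 1)
cohort <- generate_cohort(cfg, seed = 42)
report <- run_study(cohort, subgroup_stage3 = TRUE)
print(report)
```

```
Lymphoscintigraphy TI / LVA outcome study report
================================================
Patients: 45 | age 58 +/- 9 (range, 40-80; n = 45) | BMI 24.8 +/- 3.6 (range, 17.6-32.4; n = 45)
Stage counts: 2:8, 3:30, 4:7
Pre-op LELI affected: 248.5 +/- 31.2 (range, 170.8-316.7; n = 45) | contralateral: 198.0 +/- 20.3 (range, 157.4-235.5; n = 45)
TI_240 affected: 25.3 +/- 10.4 (range, 8.6-45.0; n = 45) | TI_120 affected: 25.6 +/- 10.3 (range, 8.6-45.0; n = 45)
Contralateral limbs with elevated TI (> 2): 7.2, 8.4
TI_120 vs TI_240: identical in 39/45, higher in 6 (difference 2.8 +/- 3.9 (range, 1.2-10.8; n = 6))
Stage-wise TI_240 Kruskal-Wallis p = 0.000; TI_120 p = 0.000
TI vs pre-op excess: TI_240 r = 0.481, p = 0.001 (n = 45); TI_120 r = 0.493, p = 0.001 (n = 45)
%dLELI: 1m 6.7 +/- 4.5 (range, -2.8-17.4; n = 45) | 3m 7.5 +/- 4.9 (range, -5.5-17.3; n = 45) | 6m 6.6 +/- 7.9 (range, -9.7-24.4; n = 45)
TI vs %dLELI (Spearman):
  TI_240 vs 3m: r = -0.380, p = 0.010 (n = 45)
  TI_120 vs 3m: r = -0.360, p = 0.015 (n = 45)
  ...
```

Reading the output: the affected limbs carry roughly 50 LELI units of excess
volume over the contralateral side; TI increases with clinical stage
(Kruskal-Wallis p < 0.001) and correlates positively with that pre-operative
excess; and — the study's central relationship — higher TI predicts *smaller*
post-operative volume reduction at 3 and 6 months (negative Spearman
correlations), while the 1-month change is dominated by noise. `write_report()`
serializes all of this (full precision) to `report.json` plus per-table CSVs.

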