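---
title: "Transport-index scoring, LELI volumetry, and the synthetic LVA cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport-index scoring, LELI volumetry, and the synthetic LVA cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphoti)
```

This vignette documents the models and numerical choices behind the package:
how a qualitative lymphoscintigraphy read becomes a transport index (TI), how
the 120-minute censored window is defined, what the limb-volume index measures,
which conventions the nonparametric tests follow, and exactly what the
synthetic cohort generator emulates — and does not.

## The transport index

A read grades five visual criteria of a lower-extremity lymphoscintigraphy on
the ordinal scale {0, 3, 5, 9}: transport kinetics `K` (no delay → missing
transport), dermal backflow `D` (normal → transport stop), node visualization
`N` and main-vessel visualization `V` (clearly visible → not visualized), plus
the time `T` in minutes to the first appearance of the ilio-inguinal nodes on
the serial whole-body images (acquired at 15, 30, 60, 120, 180 and 240 min).
Collateral-flow visualization `C` is recorded as a binary flag. The composite
severity score is

$$\mathrm{TI} = K + D + 0.04\,T + N + V,$$

a continuous variable between 0.6 (all grades normal, nodes at 15 min) and 45
(everything at grade 9). Two conventions make the bounds exact:

* **Non-visualized nodes score 9 on the time term.** A node that never appears
  has no appearance time; it contributes the worst grade, and consistency
  requires `N = 9` at the same time. `validate_reads()` rejects reads that
  violate this coupling rather than repairing them, because a violation
  indicates a recording error, not a borderline case.
* **The time term is capped at 9.** Literally, $0.04 \times 240 = 9.6$, which
  would make a node appearing on the final image score *worse* than a node
  that never appears, and would push the maximum TI to 45.6. Capping at the
  non-visualization score removes that inversion and makes the stated maximum
  of 45 exactly attainable. The cap only matters for 240-minute appearances,
  which the generator's default node-time distribution never produces.

`enumerate_reads()` builds all 1,216 valid reads (4 × 4 × 4 grades for K, D, V
times 19 valid node states), which the test suite uses to verify the bounds
exhaustively rather than by spot checks.

## The 120-minute window

The censored index TI120 is computed from the 15-, 60- and 120-minute images
only (the 30-minute image is deliberately omitted from this window). Given a
full read, `censor_reads()` re-derives the node state:

1. a node time on a retained frame is unchanged;
2. a node time on an omitted frame before 120 min snaps **forward** to the
   next retained frame — the earliest image on which the nodes are actually
   seen within the reduced set (30 → 60);
3. nodes first seen after 120 min become non-visualized: the time term becomes
   9 and `N` is re-scored to 9.

`K`, `D` and `V` are carried over unchanged. This is the weakest assumption
available: kinetics, backflow pattern and vessel visibility are graded from
the dynamic phase of the study, which the retained frames span, whereas node
appearance is the one criterion with an explicit time stamp. Holding `K` fixed
is a modeling decision — whether transport kinetics would be re-graded within
a 2-hour study is not defined by the scoring system; we treat the full-study
grade as the reference. Under this rule TI120 ≥ TI240 for every valid read
(censoring can only push terms up), the smallest possible positive difference
is 1.2 (a node at 30 min snapping to 60), and a node at 180 min with `N = 5`
yields exactly (9 − 7.2) + (9 − 5) = 5.8 — the two extremes observed in
practice for cohorts whose node times stay at or before 180 min.

## Volumetry

The lower extremity lymphedema index is
$\mathrm{LELI} = \sum_{i=1}^{5} c_i^2 / \mathrm{BMI}$ over circumferences (cm)
at the superior patellar edge, 10 cm above and below the patella, the lateral
malleolus and the foot dorsum. The squared form is the established definition
in the LEL literature and is the only form consistent with observed index
magnitudes (five ~35 cm circumferences at BMI 25 give ≈ 250; a linear sum
would give ≈ 7). A linear-sum variant sometimes appears in abstracts by
compression of wording; this package implements only the squared form.
Outcomes are percentage changes from the pre-operative baseline,
`100 * (pre - post) / pre`, positive for reduction — so a patient whose index
*increases* by 1.8% appears as −1.8. The index is quadratic in circumference
and inverse in BMI; both identities are property-tested.

## Nonparametric tests

All tests are two-sided with significance at p < 0.05 and no multiple-testing
correction by default, matching common practice for this study size;
`run_study(p_adjust = "holm")` applies a Holm adjustment within each timepoint
of the binary-criterion battery for sensitivity analyses.

* **Spearman** — Pearson correlation of mid-ranks (the tie-corrected
  definition). Exact permutation p for n ≤ 9 (enumerating all n!
  permutations), t approximation with n − 2 df otherwise.
* **Mann-Whitney** — U counts pairwise wins (½ per tie). Exact by enumerating
  all $\binom{n}{n_a}$ labelings for combined n ≤ 10; tie-corrected normal
  approximation (with continuity correction) otherwise.
* **Wilcoxon signed-rank** — zero differences dropped; exact by enumerating
  all $2^n$ sign assignments for n ≤ 15 nonzero pairs; tie-corrected normal
  approximation otherwise.
* **Kruskal-Wallis** — tie-corrected H with a χ² p-value on k − 1 df, used
  for the three-way stage comparison (the natural k-group extension of the
  two-group rank test; on untied two-group data H equals the squared
  Mann-Whitney z). When all pooled values are identical the tie correction
  removes all rank variance; we define H = 0, p = 1.
* **Intra-rater ICC** — ICC(A,1): two-way, absolute agreement, single
  measure, from the ANOVA mean squares. Reading passes of the same observer
  are a fixed "rater" factor, and absolute agreement (not consistency) is the
  clinically relevant notion since the TI is used on an absolute scale. Other
  ICC variants would give slightly different values; the choice is stated here
  because reports rarely specify it.

The enumeration cut-offs (9/10/15) keep the exact paths under ~0.5 s each
while covering the sample sizes where asymptotics are untrustworthy. Exact
enumeration under ties is the reason these tests are implemented in the
package: the base R implementations decline exact p-values when ties are
present. Base R (`cor.test`, `wilcox.test`, `kruskal.test`, `aov`) serves as
an independent oracle in the test suite wherever its assumptions allow.

## The synthetic cohort generator

No patient-level data are distributable for studies of this kind, so the
package ships a generator whose defaults encode a published 45-patient
unilateral-LEL LVA series:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 45 | cohort size |
| `stage_probs` | 5/45, 35/45, 5/45 | Campisi stages 2/3/4 |
| `marginals$K` | 1,16,16,12 / 45 | kinetics grades 0/3/5/9 |
| `marginals$D` | 2,7,34,2 / 45 | dermal backflow grades |
| `marginals$N` | 8,6,8,23 / 45 | node-visualization grades |
| `marginals$V` | 3,13,22,7 / 45 | vessel-visualization grades |
| `node_time_probs` | 6,5,6,5,2 / 24 | node time 15/30/60/120/180 min, given visualized |
| `collateral_prob` | 26/45 | collateral flow visible |
| `severity_link` | 0.6 | copula correlation to latent severity |
| `outcome_means` | 6.5, 7.9, 5.6 % | mean %ΔLELI at 1/3/6 months |
| `outcome_sds` | 4.9, 5.0, 6.8 % | outcome noise SD |
| `ti_outcome_rho` | 0, −0.366, −0.370 | target Spearman(TI120, %ΔLELI) |
| `bmi_dist` | 25.3 ± 3.5 | BMI, kg/m² |
| `contra_leli_dist` | 200.2 ± 18.8 | contralateral pre-op LELI |
| `excess_model` | 51.1 + 10·z + N(0, 18.8) | affected-limb LELI excess |
| `contra_elevated_prob` | 4/45 | contralateral limbs with mildly elevated TI |

**Mechanism.** One latent severity $z_i \sim N(0,1)$ per patient drives
everything: the stage (by thresholding $z$ at the stage-probability
quantiles), each ordinal component through a Gaussian copula
($w = \rho z + \sqrt{1-\rho^2}\,\varepsilon$, thresholded at the marginal
quantiles, so marginals are exact for any $\rho$), the collateral flag, the
node time, and the pre-operative excess volume. With `severity_link = 0` the
components reduce to independent draws from the stated marginals.

**Node time needs special care.** The tabulated read counts are internally
inconsistent: 23 limbs have node grade `N = 9` (never visualized) but only 21
appear in the "no visualization" column of the time criterion. The validity
constraint (no time ⟺ `N = 9`) cannot satisfy both, so the generator draws
`N` first and draws a time only when `N < 9`; the non-visualization
probability is therefore 23/45. Moreover, because the time latent and the
node-score latent share the severity $z$ (correlation $\rho^2$), conditioning
on visualization would skew a naively thresholded time variable toward early
times. The generator instead sets the time thresholds on the *conditional*
law of the time latent given visualization — a bivariate-normal tail integral
solved by `integrate()` + `uniroot()` — so that the time distribution given
`N < 9` equals `node_time_probs` exactly while remaining severity-linked.
With these conventions the expected TI has the closed form implemented in
`expected_ti()` (≈ 26.36 at the defaults: component means 5.24 + 4.64 + 5.89 +
4.71 plus the expected time term 5.87), and the generator's large-n mean
matches it; this sits slightly above the source cohort's printed mean of
25.5 ± 11.0, a gap attributable to the tabulation inconsistency and rounding,
and we match the tabulated marginals rather than the printed mean.

**Outcomes.** %ΔLELI at month $m$ is
$\mu_m - b_m \,(\mathrm{TI}_{120} - 25.5)/11.0 + N(0, \sigma_m)$ — Gaussian
noise on the percentage scale, which is how such outcomes are reported. The
reference constants 25.5/11.0 only standardize the slope's units; rank
correlations are invariant to them. `calibrate_link()` finds $b_m$ by
monotone bisection on a fixed 100,000-patient calibration sample so that the
population Spearman correlation between TI120 and the outcome hits the target
(±0.01); a zero target gives slope 0 without simulation. The 1-month target
is 0 (no correlation at 1 month), −0.366 at 3 months and −0.370 at 6 months.

**Volumetry synthesis works backwards**: the generator draws the target LELI
trajectory, then distributes the implied $\sum c_i^2 = \mathrm{LELI}\times
\mathrm{BMI}$ over the five sites using anatomically plausible weights
(relative squared contributions ≈ 0.22/0.42/0.20/0.09/0.07 for patella /
above / below / malleolus / foot, i.e. circumferences around 40/55/38/25/23 cm
at BMI 25) with 5% lognormal jitter, renormalized. `leli()` therefore
round-trips the drawn index exactly, which the pipeline tests rely on.

**Contralateral limbs** are drawn from a low-severity regime (all grades 0,
nodes by 15 or 30 min, TI 0.6 or 1.2) except for a small fraction (4/45) given
mild elevation — kinetics grade 3, optionally vessel grade 3, nodes at 30 or
60 min — whose attainable TIs are exactly {4.2, 5.4, 7.2, 8.4}, emulating the
handful of subclinically impaired contralateral limbs such cohorts contain.
The excess-model coefficients (link 10, residual SD 18.8) were chosen so the
affected-limb LELI SD is ≈ 28 and the TI–excess rank correlation lands near
the weak-to-moderate 0.3 observed clinically.

**What the generator does not emulate.** Reader disagreement (a second
reading pass must be supplied explicitly to exercise the ICC), measurement
error in circumferences beyond the site jitter, loss to follow-up and
bilateral disease (the pipeline supports missing timepoints and a `bilateral`
exclusion flag, but the generator emits complete unilateral data), covariate
effects on outcome (age, BMI, duration are drawn independently of outcome,
consistent with the absence of such associations in the source series), and
any time-correlation structure in outcomes beyond their shared dependence on
TI. Passing tests on synthetic cohorts therefore validate the *pipeline
arithmetic and the calibration machinery*, not clinical effect sizes on real
patients.

## The pipeline

`load_cohort()` validates the three CSVs with row-level diagnostics and never
repairs data silently. `run_study()` runs each analysis block independently;
a block that cannot be computed (constant TI, empty stratum, too few pairs) is
marked `computed = FALSE` with the reason, and the run continues. Outcome
analyses use affected limbs only; contralateral TIs are reported
descriptively (limbs above TI 2, the maximum attainable by an all-normal
read, are listed individually). Patients flagged `bilateral` are excluded
from outcome analyses unless `include_bilateral = TRUE`. When two reading
passes are present the analyses use pass 1 — a recorded consensus should be
stored as pass 1 — and the ICC compares the two passes' TI240. Reports are
stored at full precision (JSON/CSV); only the rendered text summary rounds
(TI to 1 decimal, rho and p to 3).

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the RNG state
(`withr::with_seed`), so cohorts, calibrations and reports are bit-reproducible
from `(config, seed)`. The package's own verification uses: exhaustive
enumeration (1,216 reads) for all TI range and censoring properties; 10⁵
draws for marginal recovery, the closed-form mean, and slope calibration; 500
replicate cohorts of n = 45 for the calibration-recovery check (mean sample
Spearman within ±0.05 of the −0.366 target, comfortably above the Monte-Carlo
error of ≈ 0.006); and combined n ≤ 8 for brute-force agreement of every exact
test path. These sizes make the full suite run in well under a minute while
leaving each check's resolution far finer than the tolerance it asserts.

## Known limitations

* The TI is a heuristic composite; the package implements it as specified and
  makes no claim that its components are optimally weighted.
* The censoring rule fixes `K`, `D`, `V` across windows; if a 2-hour study
  would genuinely re-grade kinetics, TI120 here is a lower bound on that
  variant.
* The exact Mann-Whitney path enumerates $\binom{n}{n_a}$ labelings and is
  limited to combined n ≤ 10 by default; raising `exact_limit` is possible
  but cost grows combinatorially.
* ICC is implemented for exactly two reading passes (the intra-rater design);
  multi-rater designs are out of scope.
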