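---
title: "Cooling-dose metrics and U-shaped dose-response inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooling-dose metrics and U-shaped dose-response inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooldose)
```

## The problem

Selective cerebral hypothermia delivers cooled blood to one hemisphere
through a carotid catheter, sparing the body core. In a swine focal-stroke
model, the question is not only *whether* cooling protects but *how much
cooling is best*: too little may be ineffective, while very intense cooling
may itself injure tissue. `cooldose` implements the statistical pipeline for
that question: it quantifies each animal's cooling exposure as a scalar
"dose", compares injury outcomes between cohorts, correlates dose components
with injury, and fits a quadratic dose-response curve whose vertex is the
injury-minimizing dose.

Because no per-animal data are publicly deposited for this design, the
package ships a synthetic-cohort generator that reproduces the *statistical
structure* of such an experiment. Every downstream stage is exercised, and
its calibration checked, against cohorts whose generative truth is known.

## The cooling dose

Brain temperature is recorded every 5 minutes for up to 3 hours
(37 readings). The dose below a threshold $x$ °C is the rectangle sum

$$\mathrm{AUC}_x = 5 \sum_i \max(x - T_i,\, 0) \quad \text{degree-minutes},$$

the area bounded below the threshold and above the time-temperature curve.
`compute_auc()` implements exactly this per-reading sum: fixed
$\Delta = 5$ min, no trapezoid rule, no interpolation at threshold
crossings, readings used as recorded. A series shorter than the full window
is summed over what exists, with a warning. Two thresholds are conventional:
AUC34 (moderate hypothermia benchmark) and AUC30. `compute_dose()` adds the
temperature nadir (raw minimum — no smoothing is applied before taking the
minimum), the cooling time (span of readings more than 0.5 °C below the
first reading, a proxy used because perfusion logs are not part of the data
model), the time from cooling start to the first sub-30 °C reading, and the
total time to below 30 °C when a setup time is supplied. A series that never
reaches 30 °C reports that time as absent, not as an error.

```{r}
s <- temperature_series("ex", "control", seq(0, 180, 5), rep(37, 37))
compute_dose(s)[, c("auc34", "auc30", "temp_nadir", "cooling_time")]
```

A control animal never dropping below 34 °C has AUC34 of exactly 0; for
whole-cohort analyses controls are imputed by convention at AUC34 = 0,
AUC30 = 0, cooling time = 0 and nadir exactly 37.0 °C
(`impute_control_doses()`). The nadir convention follows the tabulated
whole-cohort rule even though untreated animals in practice sit slightly
above 37 °C — fixing it makes analyses reproducible.

## Group comparison and correlations

`welch_t_test()` performs the unpaired two-sided t-test with Welch's
correction (Welch–Satterthwaite df); `group_summary()` reports medians with
quartiles per group, the format injury tables use, with the Welch p-value
alongside. Note the deliberate mismatch — a mean-based test under a
median-based display — which mirrors the stated analysis; a rank test can be
swapped in by the user but is not the default. No multiple-testing
adjustment is made by default (a Holm option exists).

Correlations between cooling parameters and outcomes are Pearson
coefficients tested by transforming with Fisher's z:
$z = \operatorname{atanh}(r)\sqrt{n-3}$ referred to the standard normal,
two-sided. This normal-reference test — not the t-based test of
`cor.test()` — is used throughout, so printed claims such as $r = 0.48,
n = 17 \Rightarrow p \approx 0.05$ are directly recomputable:

```{r}
fisher_z_test(0.48, 17)$p
fisher_z_test(-0.59, 17)$p
```

`correlation_matrix()` evaluates every (parameter, outcome) pair either
within the treated cohort or across all animals with controls imputed.
Missing values are dropped pairwise and counted. With a U-shaped
dose-response whose vertex lies inside the treated dose range, the two
tables can disagree in sign: within the treated cohort most animals sit on
the rising limb (more cooling, more injury), while adding untreated controls
at dose zero — with their higher injury — flips the correlation negative.
`ushape_demo_config()` generates a cohort constructed to exhibit this
reversal.

## Quadratic dose-response and the minimizing dose

`fit_quadratic()` fits $E(Y\mid x) = a + bx + cx^2$ by OLS on the outcome's
natural scale. $b$ is the slope at the origin (the incremental effect of the
first unit of cooling), $c$ the concavity ($c > 0$: U-shaped), and the
injury-minimizing dose is the vertex $x^\* = -b/(2c)$, defined only when
$c > 0$. Numerically, the vertex is withheld whenever $c \le 10^{-12}$
(outcome units per degree-minute²): a fit to linear data returns $c$ at
rounding-error scale, and dividing by it would manufacture a meaningless
vertex.

`bootstrap_quadratic()` provides ordinary non-parametric (pairs) bootstrap
inference with **studentized** (bootstrap-t) intervals: each replicate
resamples animals with replacement, refits, and contributes
$(\hat\theta^* - \hat\theta)/\widehat{SE}^*$. The studentizing SE is the
analytic OLS standard error for $b$ and $c$, and a delta-method SE for the
vertex,

$$\widehat{SE}^2(x^\*) = g^\top V g, \qquad
  g = \left(-\tfrac{1}{2c},\; \tfrac{b}{2c^2}\right),$$

with $V$ the $(b, c)$ covariance block. Analytic inner SEs were chosen over
a nested bootstrap because at cohort sizes near 30 the nested resample is
noisy and slow; the choice is a documented default, not the only defensible
one. Replicates whose resampled design has fewer than three distinct doses
are discarded; replicates with $c \le 10^{-12}$ cannot contribute a vertex
and are excluded from its distribution but counted (`n_degenerate`). If more
than half the usable replicates are degenerate the vertex interval is
withheld with a diagnostic rather than reported from a minority of
replicates. The fraction of replicates with $c > 0$ is reported as evidence
of a U-shape. Defaults: $B = 2000$, level 0.95, and a mandatory seed.

On noise-free quadratic data every replicate refits exactly; the studentized
statistic is taken as 0 when both the deviation and its SE vanish, so
intervals collapse to the point estimate instead of propagating 0/0.

`predict_curve()` evaluates the fitted parabola on a grid with pointwise
percentile bands across replicate curves (a simultaneous band is not
attempted). The bands are clamped outward to contain the point-estimate
curve at every grid point; raw percentile bands do not guarantee that
containment, and the clamp makes the band's minimal semantics — "covers the
reported fit" — hold by construction.

## What the synthetic cohort emulates

`sim_config()` defaults encode the target design: 13 controls and 17
treated animals; readings every 5 min for 180 min; treated animals at
baseline 37 °C until a setup time drawn uniformly from (22, 144) min, then
an exponential approach $T(t) = m + (37 - m)e^{-(t - t_s)/\tau}$ to a nadir
$m \sim U(20.3, 27.5)$ °C for a cooling duration drawn from (36, 150) min,
plus Gaussian reading noise (SD 0.3 °C), clipped to (15, 40) °C. The
uniform ranges are the published per-animal minima and maxima; the
exponential shape is a one-parameter choice consistent with the rapid
monotone descents seen in representative cooling curves (no functional form
is published), and $\tau = 20$ min makes the descent from 37 °C cross 30 °C
in about 15 min for a typical nadir, matching the published median time to
< 30 °C. Rewarming is not modelled: if cooling ends before 180 min the
series holds its last cooled value, keeping the full 37-point grid. Controls
receive truncated noise (never below 34 °C) so their AUC34 is *exactly* zero
by construction.

Outcomes follow the generative quadratic with vertex at 515 degree-minutes:
$c = 4 \times 10^{-6}$, $b = -2 \cdot c \cdot 515 = -4.12 \times 10^{-3}$,
and intercept $a = 1.89$ cm³, the control-group total-pathology median —
a loose emulation of scale, not a fit to data. Outcome noise SD 0.45 keeps
draws clipped at zero below 5 % (the minimum mean outcome is 0.83, about
1.84 SD above zero); clip events are counted and surfaced. MRI percent is
the same dose signal scaled by 0.0265 (the ratio of the control medians),
and the largest-pathology volume is a uniform 0.45–0.65 fraction of the
total, structurally guaranteeing `largest <= total`. All sampling flows
through per-animal substreams derived deterministically from
(seed, animal index), so identical configs give byte-identical CSVs.

What the simulator deliberately does **not** reproduce: physiologic
covariates (hemodynamics, blood gases), core-vs-brain temperature
gradients, multi-probe geometry, rewarming, or any empirical joint
distribution of setup time and nadir (they are sampled independently).
Passing tests therefore certify the *statistical machinery* — dose
computation, test calibration, interval coverage — under a known truth, not
fidelity to any particular animal dataset.

## Calibration results the test suite computes

Two simulation studies back the inference code (both run in the test
suite; sizes chosen to keep the full suite under a couple of minutes):

- **Recovery.** At 200 animals and low outcome noise (SD 0.05) the fitted
  vertex lands within 2 % of the generative 515 degree-minutes; with noise
  removed entirely the coefficients are recovered beyond six significant
  digits.
- **Coverage.** At the design scale (13 + 17 animals, default noise), the
  studentized 95 % interval for the vertex covers the truth in about 92–93 %
  of 500 simulated cohorts (B = 999) — within the 95 % ± 3 % Monte Carlo
  acceptance band, with the mild undercoverage expected of bootstrap-t
  intervals on a ratio at n = 30.

A null-concavity study (linear truth) shows the replicate fraction with
$c > 0$ hovering near one half and the vertex interval being withheld, as
it should be when no U-shape exists.

## Numerical and degenerate-input policy, in one place

- Quartiles: linear interpolation between order statistics (type 7), stated
  so other implementations can match tables exactly.
- AUC thresholds restricted to (0, 45) °C; empty series error; short series
  warn and sum what exists.
- Zero variance makes a Pearson correlation undefined: labelled error, never
  a silent zero. $|r| = 1$ makes Fisher's z infinite: labelled error.
- Welch's test with two constant equal groups returns $p = 1$ by convention.
- Rank-deficient quadratic designs (fewer than three distinct doses) error
  at fit time and are discarded as replicates at bootstrap time.
- Temperatures outside (10, 45) °C, negative volumes, `largest > total`,
  duplicate ids and unknown group labels are caught by `validate_tables()`
  before the pipeline runs.

## Limitations

The vertex CI procedure (delta-method studentization, degenerate replicates
excluded and counted) is one reasonable policy among several; with data
whose concavity is weakly identified the interval is withheld rather than
extrapolated, which is conservative. The pipeline fits each outcome
marginally — no multivariate or mixed-effects structure — and makes no
causal claim: the minimizing dose is a feature of a fitted curve on
observational (here, simulated) cohorts.
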