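---
title: "Methods: time-stratified case-crossover DLNM for temperature and hospital visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover DLNM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the design

`ccdlnm` estimates short-term associations between daily ambient
temperature and acute health events — the motivating application is
alcohol- and substance-related hospital visits at ZIP-code resolution —
while controlling confounding by design rather than by covariate
adjustment.

Each hospital visit (case) is compared with the *same person's*
exposure on matched referent days: every other day in the same calendar
year and month that falls on the same day of week. This
**time-stratified case-crossover** design forms strata of one case day
plus 2–4 control days. Matching on year–month controls season and
long-term trend; matching on weekday controls weekly admission
patterns; and because each stratum is one person's own experience, all
stable personal characteristics cancel. With referents spaced exactly 7
days apart and exposure lags restricted to 0–6 days, the case and
control lag windows never overlap.

## The model

Within stratum $c$, the probability that subject $i$'s visit fell on a
particular day is modelled by a conditional logistic regression whose
linear predictor contains distributed-lag non-linear (DLNM) terms for
temperature and relative humidity:

$$\mathrm{logit}\,\Pr(Y_{ci}=1) \;=\; \alpha_c
  + \sum_{l=0}^{6} s(T, df)_{lci}
  + \sum_{l=0}^{6} s(RH, df)_{lci},$$

where $\alpha_c$ are stratum intercepts that cancel in the conditional
likelihood, and $s(\cdot,df)_l$ are lag-specific natural cubic spline
terms. The DLNM **cross-basis** realizes these sums as a tensor
product: with exposure-basis functions $v_j$ ($j = 1..df_{var}$) and
lag-basis functions $L_k$ ($k = 1..df_{lag}$), row $i$ of the design
block is

$$x_{i,(j,k)} \;=\; \sum_{l=0}^{L} v_j(T_{i,l})\, L_k(l),$$

so one coefficient vector $\theta$ of length
$df_{var}\times df_{lag}$ describes a smooth exposure–lag–response
surface. The relative-humidity block mirrors the temperature block's
structure.

The conditional log-likelihood with one case per stratum is

$$\ell(\theta) = \sum_c \Big[ x_{case}^\top\theta -
  \log \sum_{r \in c} \exp(x_r^\top\theta) \Big],$$

a smooth concave function maximized here by damped Newton–Raphson with
analytic gradient and Hessian (`fit_clr()`), the log-sum-exp computed
with per-stratum max subtraction. The covariance is the inverse
observed information. Strata in which no covariate varies contribute a
$\theta$-free constant and are dropped with a logged count.

Results are reported as the **cumulative percent change**
$100(e^\eta-1)$, where $\eta$ is the sum over lags of lag-specific log
rate ratios contrasting a temperature with a reference value
(`cumulative_contrast()`); its variance comes from the delta method,
$g^\top \Sigma g$ with $g$ the analytic gradient of the contrast.
Centring happens at prediction time, never by transforming the design
matrix, so the fitted likelihood is independent of the reference
choice.

## Tunable parameters

* **`max_lag`** (days; default 6). Captures the most acute effects
  while keeping case/control lag windows disjoint under 7-day referent
  spacing. A secondary lag 0–1 analysis is run as a *separate* model
  with `max_lag = 1` and an unconstrained (one column per lag) lag
  basis; the lag-{0,1} subset contrast from the 0–6 fit is also
  reported, since both readings of a "two lag day" analysis are
  defensible.
* **`df_var`, `df_lag`**. Spline degrees of freedom along the exposure
  and lag dimensions. The default selection grid is
  $df_{var}\in\{3,4\}\times df_{lag}\in\{2,..,5\}$ (8 models), chosen
  by minimum AIC ($-2\hat\ell + 2k$) per cause on the full-cause data;
  stratified analyses reuse the selected pair. AIC ties within $10^{-6}$
  go to the smaller total df (parsimony).
* **Knot placement.** Exposure-dimension interior knots sit at equally
  spaced percentiles of the pooled case+control lagged exposure
  ($df_{var}=3$: 33.3rd/66.7th), boundary knots at the observed
  min/max; the lag basis is a natural cubic spline in $\log(lag+1)$
  with an intercept column and interior knots equally spaced on the
  log-lag scale ($df_{lag}=4$: 2 interior knots). These are the
  conventional DLNM defaults; the source analyses do not state their
  knot rules, so convention is followed deliberately.
* **`reference`** temperature (°C). Defaults to the minimum observed
  daily exposure over the analysis period (the convention of reporting
  changes relative to the period minimum); any finite override is
  accepted. Because contrasts are formed at prediction time, this is a
  reporting choice only.
* **Percentile source.** Named contrasts (50th/75th/90th/99th) are
  computed over the pooled lagged case+control exposure distribution by
  default; `percentile_source = "case"` switches to case-day lag-0
  values. The source analyses are ambiguous on this point, so both are
  exposed.

## Relative humidity

The gridded inputs carry temperature, specific humidity $q$ (kg/kg) and
surface pressure $p$ (hPa). Relative humidity is derived per grid cell
as $100\,e/e_s$ with vapor pressure $e = qp/(0.622+0.378q)$ and Magnus
saturation pressure $e_s = 6.112\exp(17.67T/(T+243.5))$, clipped to
$[0,100]$. RH is non-linear in its inputs, so it is computed at the
cell level *before* population weighting; spatial aggregation is then
the linear map $\bar x_u = \sum_c w_{uc} x_c$ with non-negative weights
summing to one per unit.

## What the synthetic generator emulates — and what it does not

`simulation_truth()` defines a complete data-generating process:

* **Weather**: per grid cell, daily temperature = seasonal sinusoid
  (mean 10 °C, amplitude 12 °C, peak in mid-July) + cell offset +
  AR(1) noise (coefficient 0.7, innovation sd 2.5 °C) — the
  persistence and annual cycle of mid-latitude daily means. Humidity is
  generated by inverting a target RH (its own seasonal cycle, clamped
  to [5, 95]) at the simulated temperature and pressure, so derived RH
  is in range by construction.
* **Cases**: daily counts per unit are Poisson with log-mean =
  baseline(unit, season) + $\sum_l f(T_{d-l}, l)$, where $f$ is a known
  surface (null, linear, or threshold family) that vanishes at its
  reference temperature at every lag. Conditional on one case in a
  stratum, the case day is multinomial with softmax probabilities of
  the true linear predictor — exactly the conditional-logistic form the
  model assumes, which is what makes parameter recovery a meaningful
  check. Counts are expanded to admission records with diagnosis codes
  drawn from a cause map, age/sex margins, and an optional
  contamination fraction of invalid fields to exercise the exclusion
  rules.
* The default study is 30 units × 12 cells × 4 years. The
  **calibration truths** used in the coverage and recovery experiments
  are smaller (6 units × 4 cells × 2 years, baseline calibrated to a
  target case count) and set the baseline's *seasonal* amplitude to
  zero: unit effects cancel exactly in the conditional likelihood, but
  within-month baseline drift is genuine residual confounding that
  month strata only partly control, and the calibration experiments are
  meant to measure the estimator, not that design limitation. The
  full default truth keeps a seasonal baseline (amplitude 0.15 on the
  log scale) for realism.

The generator does **not** attempt real geography, true ICD code
frequency distributions, or the spatial covariance structure of a
reanalysis product. Passing tests therefore demonstrate correctness of
the statistical machinery under a faithful idealization — not that any
particular real-data estimate is reproducible, which would require the
restricted hospital microdata.

## Numerical choices and degenerate inputs

* Newton iterations start at $\theta=0$, halve the step on likelihood
  decrease, and declare convergence at gradient sup-norm $<10^{-8}$;
  non-convergence, separation ($\|\theta\|_\infty>10^4$) and singular
  information are *flagged* on the result, never thrown.
* Events whose stratum (including the lag window of its earliest
  referent) is not fully covered by the exposure series are dropped
  with a logged count rather than imputed; a gap *inside* the covered
  range is an error naming the first missing (unit, date).
* Tertile ties at cut points break by unit id, lexically; tertile sizes
  differ by at most one unit.
* ICD matching is dot-insensitive prefix matching, so code blocks can
  be specified at mixed granularity ("304.3" covers 304.30–304.39);
  only diagnosis positions 1–4 are ever ingested.
* "Inaccurate" admission dates are operationalized as unparseable or
  outside the configured study period.
* Day-of-week arithmetic uses civil dates in the proleptic Gregorian
  calendar; no time zones.

## Problem sizes used in the shipped experiments

The packaged tests run the coverage and recovery experiments at 200
replicates (expected 1,000 cases per replicate under the null surface;
2,000 under the linear surface with cumulative log rate ratio 0.2 per
+10 °C), checking empirical 95% CI coverage against [0.90, 0.99] and
mean recovery within 3 Monte-Carlo standard errors. The acceptance
script re-runs the same experiments at 100 replicates and drives the
full pipeline (exposure aggregation → exclusions → classification →
strata → fit → curves → humidity-sensitivity comparison) on an 8-unit,
3-year synthetic bundle. These sizes give Monte-Carlo error small
enough for the stated checks while keeping a laptop run in minutes.

## Known limitations

* Only the time-stratified referent scheme is implemented; no
  bidirectional or other referent designs.
* Natural cubic splines only; no penalized or B-spline alternatives.
* No robust/sandwich variance and no Efron/Breslow tie handling — with
  one case per stratum the plain conditional likelihood is exact.
* The packaged cause map is an illustrative grouping of ICD-9-CM code
  blocks, not a certified reproduction of any licensed grouper; users
  supply their own map for substantive work.
* Contrasts against the observed period minimum sit in the sparse tail
  of the exposure distribution and carry wide intervals — visible in
  the synthetic runs exactly as in published analyses of this design.
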