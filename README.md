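# ccdlnm

Time-stratified case-crossover analysis with distributed lag non-linear
models (DLNM), for estimating short-term associations between daily
ambient temperature and acute health events — built around the study of
alcohol- and substance-related hospital visits at ZIP-code resolution,
and usable for any admission-records + gridded-weather setting of the
same shape.

## Who this is for

Environmental epidemiologists and biostatisticians who want a tested,
end-to-end implementation of the full chain:

1. **Exposure** — population-weighted aggregation of gridded daily
   weather to ZIP-level series, with relative humidity derived per grid
   cell from temperature, specific humidity and pressure
   (Magnus saturation vapor pressure) before spatial averaging.
2. **Cohort** — ICD-9-CM cause classification from the first four
   diagnosis positions (dot-insensitive prefix patterns; one admission
   may count toward several causes), completeness exclusions with a
   flow report, tract-to-ZIP area-weighted social-vulnerability (SVI)
   tertiles.
3. **Design** — time-stratified referents (same year, month and
   weekday), strata of one case day plus 2–4 control days, 0–6-day
   lagged exposures; case and control lag windows never overlap.
4. **Model** — natural-spline cross-bases for temperature and relative
   humidity, conditional logistic regression maximized by damped
   Newton–Raphson with analytic derivatives, AIC selection of spline
   degrees of freedom over the {3,4} × {2..5} grid.
5. **Effects** — cumulative percent change in visit rates at any
   temperature relative to a reference (default: the period minimum),
   with delta-method 95% CIs; exposure-response curves, percentile
   contrasts, stratified analyses (location, sex, age group, SVI
   tertile), a lag 0–1 secondary model, and a no-humidity sensitivity
   comparison.
6. **Simulation** — a generator with a known exposure–lag–response
   surface whose within-stratum case-day probabilities follow the
   conditional-logistic form exactly, enabling coverage and
   parameter-recovery experiments without restricted microdata.

The model is, per matched stratum *c*,

```
logit Pr(Y_ci = 1) = alpha_c + sum_{l=0..6} s(T, df)_lci + sum_{l=0..6} s(RH, df)_lci
```

with the `s(.)_l` realized as a tensor-product cross-basis
`x_(j,k) = sum_l v_j(T_l) L_k(l)`; the stratum intercepts `alpha_c`
cancel in the conditional likelihood. See the methods vignette
(`vignettes/case-crossover-dlnm.Rmd`) for the full account.

## Worked example

Simulate a complete input bundle with a known linear surface
(cumulative log rate ratio 0.25 per +10 °C), then run the pipeline:

```r
library(ccdlnm)

truth <- simulation_truth(n_units = 8L, n_cells = 4L, years = 3,
                          baseline = list(log_rate = -1.6),
                          surface = list(family = "linear", per10 = 0.25,
                                         reference = 0),
                          seed = 42L)
paths <- write_fixture_bundle(truth, file.path(tempdir(), "bundle"))

cfg <- list(admissions = paths$admissions, grid = paths$grid,
            crosswalk = paths$crosswalk, area_weights = paths$area_weights,
            tract_svi = paths$tract_svi, cause_map = paths$cause_map,
            city_units = read.csv(paths$city_units)$unit_id,
            causes = "alcohol", var_df = 3L, lag_df = 4L,
            stratified = FALSE)
res <- run_analysis(cfg)
print(res)
print(res$causes$alcohol$curves$overall)
```

```
case-crossover DLNM analysis: 1 cause(s)
  alcohol: 2159 events, df_var=3 df_lag=4 (fixed), AIC 6376.6
cumulative exposure-response curve: 100 grid points, reference -17.2 C, lags 0-6
 prob fahrenheit at_temperature       eta  variance percent_change     ci_low   ci_high
 0.50       58.9       14.95194 0.9695189 0.4185587       163.6676 -25.807090  837.0247
 0.75       69.2       20.64537 1.2641912 0.4063033       254.0228   1.498356 1134.8197
 0.90       74.9       23.84710 1.4267191 0.4205587       316.5012  16.844380 1384.6519
 0.99       83.7       28.70374 1.6688951 0.4890387       430.6302  34.752115 1989.5285
```

Reading the table: moving every lag day 0–6 from the coldest observed
day (−17.2 °C) to the 75th-percentile temperature (20.6 °C = 69.2 °F)
multiplies the visit rate by `exp(1.264) ≈ 3.5`, i.e. a cumulative
+254% (95% CI, +1.5% to +1135%) — wide, because the reference sits in
the sparse cold tail. The truth-implied contrast for this draw is
`0.947` on the log scale, inside the interval. The no-humidity
sensitivity refit tracks the main estimates closely here
(`res$causes$alcohol$sensitivity`: R = 1.000, slope = 1.034).

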