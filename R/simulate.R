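# evaluate expr with a temporarily seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Ground truth for a synthetic case-crossover study
#'
#' Bundles everything the generator needs: the weather model (seasonal
#' mean cycle, AR(1) day-to-day persistence, per-cell offsets), the
#' humidity/pressure model, the study geography (units, grid cells,
#' period), the baseline visit process, and the true
#' exposure-lag-response surface injected into the case process.
#'
#' The surface is stored as a named family plus parameters and must
#' vanish at its reference temperature at every lag (identifiability of
#' contrasts). Supported families: `"null"` (no effect), `"linear"`
#' (cumulative log rate ratio `per10 / 10` per degree C above
#' `reference`, spread uniformly over lags 0..max_lag), `"threshold"`
#' (linear above a threshold, flat below).
#'
#' Defaults describe a 4-year, 30-unit, 12-cell study: a mid-latitude
#' seasonal temperature cycle (mean 10 C, amplitude 12 C, AR(1) 0.7,
#' innovation sd 2.5 C) with humidity generated so that derived relative
#' humidity stays within (5, 100).
#'
#' @param n_units,n_cells Number of ZIP-level units and weather grid cells.
#' @param years Length of the simulated period (years).
#' @param start First day (ISO date string).
#' @param weather List overriding weather parameters: `mean`, `amplitude`,
#'   `phase` (day of year of the upward zero-crossing), `ar`
#'   (in (-1, 1)), `noise_sd` (innovation sd), `cell_offset_sd`,
#'   `rh_mean`, `rh_amplitude`, `rh_sd`, `pressure_mean`, `pressure_sd`.
#' @param baseline List overriding the visit process: `log_rate`
#'   (per-unit-day log expected cases), `unit_sd` (sd of unit random
#'   effects), `season_amplitude` (log-scale seasonal cycle).
#' @param surface List: `family`, `per10`, `reference`, `threshold`.
#' @param max_lag Maximum lag the surface acts over (default 6).
#' @param seed Default seed recorded with the truth.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_units = 30L, n_cells = 12L, years = 4,
                             start = "2001-01-01",
                             weather = list(), baseline = list(),
                             surface = list(), max_lag = 6L, seed = 1L) {
  w <- utils::modifyList(list(
    mean = 10, amplitude = 12, phase = 105, ar = 0.7, noise_sd = 2.5,
    cell_offset_sd = 1, rh_mean = 55, rh_amplitude = 15, rh_sd = 8,
    pressure_mean = 1010, pressure_sd = 5), weather)
  if (abs(w$ar) >= 1) stop("AR(1) coefficient must be in (-1, 1)",
                           call. = FALSE)
  b <- utils::modifyList(list(
    log_rate = -3, unit_sd = 0.3, season_amplitude = 0.15), baseline)
  s <- utils::modifyList(list(
    family = "linear", per10 = 0.2, reference = 0, threshold = 10), surface)
  s$family <- match.arg(s$family, c("null", "linear", "threshold"))
  structure(list(
    n_units = as.integer(n_units), n_cells = as.integer(n_cells),
    years = years, start = as_date_strict(start),
    n_days = as.integer(round(years * 365.25)),
    weather = w, baseline = b, surface = s,
    max_lag = as.integer(max_lag), seed = as.integer(seed)
  ), class = "simulation_truth")
}

#' True exposure-lag-response surface of a simulation truth
#'
#' Evaluates the injected log-rate contribution at a temperature and lag.
#' At `temperature = reference` the surface is exactly zero for all lags.
#'
#' @param truth A [simulation_truth()].
#' @param temperature Degrees C (vectorized).
#' @param lag Lag in days, 0..max_lag (vectorized with `temperature`).
#' @return Log-rate contribution(s).
#' @export
surface_value <- function(truth, temperature, lag) {
  s <- truth$surface
  w <- 1 / (truth$max_lag + 1)  # uniform lag weights
  switch(s$family,
    null = rep(0, length(temperature)),
    linear = (s$per10 / 10) * w * (temperature - s$reference),
    threshold = (s$per10 / 10) * w *
      (pmax(temperature - s$threshold, 0) -
         pmax(s$reference - s$threshold, 0))
  )
}

#' True cumulative log rate ratio at a temperature versus the reference
#'
#' @param truth A [simulation_truth()].
#' @param at Temperature, deg C.
#' @param lags Lag subset (default all).
#' @return Scalar cumulative log rate ratio.
#' @export
true_cumulative_logrr <- function(truth, at, lags = 0:truth$max_lag) {
  sum(surface_value(truth, rep(at, length(lags)), lags)) -
    sum(surface_value(truth, rep(truth$surface$reference, length(lags)),
                      lags))
}

#' Simulate gridded daily weather
#'
#' Per cell, daily mean temperature follows a seasonal sinusoid plus a
#' cell offset plus AR(1) noise:
#' `T(d) = mean + amplitude * sin(2 pi (d - phase) / 365.25) + offset + e(d)`,
#' `e(d) = ar * e(d-1) + innovation`. Specific humidity is generated by
#' inverting a target relative humidity (its own seasonal cycle, clamped
#' to [5, 95]) at the simulated temperature and pressure, so that
#' relative humidity recomputed downstream lies in (5, 100) by
#' construction.
#'
#' @param truth A [simulation_truth()].
#' @param seed Seed (default: the truth's).
#' @return Grid-series data frame (`cell_id`, `date`, `temperature`,
#'   `specific_humidity`, `pressure`).
#' @export
simulate_weather <- function(truth, seed = truth$seed) {
  w <- truth$weather
  n <- truth$n_days
  days <- seq(truth$start, by = "day", length.out = n)
  doy <- as.numeric(days - truth$start) + as.POSIXlt(truth$start)$yday
  with_seed(seed, {
    offsets <- stats::rnorm(truth$n_cells, 0, w$cell_offset_sd)
    out <- vector("list", truth$n_cells)
    for (c in seq_len(truth$n_cells)) {
      innov <- stats::rnorm(n, 0, w$noise_sd)
      e <- as.numeric(stats::filter(innov, w$ar, method = "recursive"))
      temp <- w$mean + w$amplitude * sin(2 * pi * (doy - w$phase) / 365.25) +
        offsets[c] + e
      pres <- w$pressure_mean + stats::rnorm(n, 0, w$pressure_sd)
      rh_target <- w$rh_mean +
        w$rh_amplitude * sin(2 * pi * (doy - w$phase - 40) / 365.25) +
        stats::rnorm(n, 0, w$rh_sd)
      rh_target <- pmin(pmax(rh_target, 5), 95)
      q <- specific_humidity_for_rh(rh_target, temp, pres)
      out[[c]] <- data.frame(
        cell_id = sprintf("cell%02d", c), date = days,
        temperature = temp, specific_humidity = q, pressure = pres,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# expand an ICD-9 pattern to a plausible full code (dot after 3 digits)
pattern_to_code <- function(p) {
  raw <- gsub(".", "", p, fixed = TRUE)
  raw <- paste0(raw, strrep("0", max(0, 4L - nchar(raw))))
  paste0(substr(raw, 1, 3), ".", substr(raw, 4, nchar(raw)))
}

#' Simulate admission records driven by the true surface
#'
#' Daily case counts per unit are Poisson with
#' `log mean = baseline(d, unit) + sum_l surface(T at lag l, l)`; counts
#' are expanded to one admission record per case, with a first diagnosis
#' code drawn from the target cause's pattern set (remaining positions
#' filled with non-matching codes), ages and sexes from configured
#' margins, and an optional contamination fraction of records with a
#' randomly blanked field to exercise the exclusion rules.
#'
#' @param truth A [simulation_truth()].
#' @param exposure Unit-level exposure table (from
#'   [build_exposure_table()] on simulated weather).
#' @param causes A [cause_map()]; records are generated for
#'   `target_cause`.
#' @param target_cause Cause name (default: first in `causes`).
#' @param contamination Fraction of records with a missing/invalid field
#'   (default 0).
#' @param seed Seed (default: the truth's, offset by 1).
#' @return Admissions data frame (`record_id`, `admission_date`,
#'   `unit_id`, `dx1`..`dx4`, `age`, `sex`, `admission_type`).
#' @export
simulate_admissions <- function(truth, exposure, causes = example_cause_map(),
                                target_cause = names(causes)[1L],
                                contamination = 0, seed = truth$seed + 1L) {
  stopifnot(inherits(causes, "cause_map"), target_cause %in% names(causes))
  L <- truth$max_lag
  exposure$date <- as_date_strict(exposure$date)
  exposure <- exposure[order(exposure$unit_id, exposure$date), , drop = FALSE]
  units <- unique(exposure$unit_id)
  doy0 <- as.POSIXlt(min(exposure$date))$yday

  with_seed(seed, {
    unit_eff <- named(stats::rnorm(length(units), 0, truth$baseline$unit_sd),
                      units)
    recs <- vector("list", length(units))
    for (ui in seq_along(units)) {
      u <- units[ui]
      ex <- exposure[exposure$unit_id == u, , drop = FALSE]
      temp <- ex$temperature
      nd <- length(temp)
      if (nd <= L) next
      idx <- (L + 1L):nd
      cum <- numeric(length(idx))
      for (l in 0:L) {
        cum <- cum + surface_value(truth, temp[idx - l], l)
      }
      doy <- doy0 + as.numeric(ex$date[idx] - min(exposure$date))
      lmu <- truth$baseline$log_rate + unit_eff[u] +
        truth$baseline$season_amplitude *
          sin(2 * pi * (doy - truth$weather$phase) / 365.25) + cum
      counts <- stats::rpois(length(idx), exp(lmu))
      tot <- sum(counts)
      if (tot == 0L) next
      recs[[ui]] <- data.frame(
        admission_date = rep(ex$date[idx], counts),
        unit_id = rep(u, tot), stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, recs)
    if (is.null(recs) || nrow(recs) == 0L) {
      return(data.frame(record_id = character(), admission_date = character(),
                        unit_id = character(), dx1 = character(),
                        dx2 = character(), dx3 = character(),
                        dx4 = character(), age = numeric(),
                        sex = character(), admission_type = character()))
    }
    n <- nrow(recs)
    codes <- vapply(causes[[target_cause]], pattern_to_code, "")
    filler <- c("460.0", "786.2", "719.4", "401.9")
    age_breaks <- c(0, 25, 45, 65, 90)
    age_probs <- c(0.15, 0.50, 0.30, 0.05)
    grp <- sample.int(4L, n, replace = TRUE, prob = age_probs)
    age <- floor(stats::runif(n, age_breaks[grp], age_breaks[grp + 1L]))
    rec <- data.frame(
      record_id = sprintf("r%07d", seq_len(n)),
      admission_date = format(recs$admission_date, "%Y-%m-%d"),
      unit_id = recs$unit_id,
      dx1 = sample(codes, n, replace = TRUE),
      dx2 = sample(filler, n, replace = TRUE),
      dx3 = sample(filler, n, replace = TRUE),
      dx4 = sample(filler, n, replace = TRUE),
      age = age,
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.4, 0.6)),
      admission_type = sample(c("inpatient", "outpatient"), n,
                              replace = TRUE, prob = c(0.75, 0.25)),
      stringsAsFactors = FALSE)
    if (contamination > 0) {
      hit <- which(stats::runif(n) < contamination)
      fld <- sample(c("sex", "age", "admission_date", "unit_id"),
                    length(hit), replace = TRUE)
      for (i in seq_along(hit)) {
        rec[hit[i], fld[i]] <- if (fld[i] == "age") NA else ""
      }
    }
    rec
  })
}

#' Example cause map for the six study causes
#'
#' An illustrative (not certified) grouping of ICD-9-CM code blocks into
#' the six causes analyzed by the pipeline: alcohol-related disorders,
#' substance-related disorders and the four substance sub-causes
#' (cannabis, cocaine, opioids, sedatives).
#'
#' @return A [cause_map()].
#' @export
example_cause_map <- function() {
  path <- system.file("extdata", "cause_map_example.yaml",
                      package = "ccdlnm")
  if (nzchar(path)) return(read_cause_map(path))
  # fallback when running from a source checkout
  cause_map(list(
    alcohol = c("291", "303", "305.0"),
    substance = c("292", "304", "305.2", "305.3", "305.4", "305.5",
                  "305.6", "305.7", "305.8", "305.9"),
    cannabis = c("304.3", "305.2"),
    cocaine = c("304.2", "305.6"),
    opioids = c("304.0", "304.7", "305.5"),
    sedatives = c("304.1", "305.4")
  ))
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every file the pipeline ingests -- admissions, gridded weather,
#' the population-weight crosswalk, the tract-to-unit area-weight
#' crosswalk, tract SVI values, the in-city unit list, an example cause
#' map, and a truth manifest recording the surface family, parameters and
#' seed -- all as plain delimited text / YAML.
#'
#' @param truth A [simulation_truth()].
#' @param out_dir Destination directory.
#' @param seed Seed (default: the truth's).
#' @param contamination Fraction of contaminated admission records
#'   (default 0.02, to exercise the exclusion rules on read-back).
#' @param overwrite Allow writing into an existing bundle directory.
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(truth, out_dir, seed = truth$seed,
                                 contamination = 0.02, overwrite = FALSE) {
  if (dir.exists(out_dir) &&
      length(list.files(out_dir)) > 0L && !overwrite) {
    stop("bundle directory exists and is non-empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  units <- sprintf("unit%03d", seq_len(truth$n_units))
  cells <- sprintf("cell%02d", seq_len(truth$n_cells))

  grid <- simulate_weather(truth, seed)
  xw <- with_seed(seed + 2L, {
    do.call(rbind, lapply(units, function(u) {
      k <- sample(1:3, 1L)
      cs <- sample(cells, k)
      w <- stats::runif(k)
      data.frame(unit_id = u, cell_id = cs, weight = w / sum(w),
                 stringsAsFactors = FALSE)
    }))
  })
  exposure <- build_exposure_table(grid, xw)
  causes <- example_cause_map()
  adm <- simulate_admissions(truth, exposure, causes,
                             contamination = contamination,
                             seed = seed + 1L)
  svi_tabs <- with_seed(seed + 3L, {
    tracts <- sprintf("tract%04d", seq_len(2L * truth$n_units))
    tract_svi <- data.frame(tract_id = tracts,
                            svi_value = round(stats::runif(length(tracts)), 4),
                            stringsAsFactors = FALSE)
    area <- do.call(rbind, lapply(seq_along(units), function(i) {
      tr <- tracts[c(2L * i - 1L, 2L * i)]
      w <- stats::runif(2L)
      data.frame(tract_id = tr, unit_id = units[i], weight = w / sum(w),
                 stringsAsFactors = FALSE)
    }))
    list(tract_svi = tract_svi, area = area)
  })
  city_units <- units[seq_len(max(1L, round(0.3 * truth$n_units)))]

  paths <- list(
    admissions = file.path(out_dir, "admissions.csv"),
    grid = file.path(out_dir, "grid_weather.csv"),
    crosswalk = file.path(out_dir, "crosswalk_population.csv"),
    area_weights = file.path(out_dir, "crosswalk_area.csv"),
    tract_svi = file.path(out_dir, "tract_svi.csv"),
    city_units = file.path(out_dir, "city_units.csv"),
    cause_map = file.path(out_dir, "cause_map.yaml"),
    truth = file.path(out_dir, "truth_manifest.yaml")
  )
  utils::write.csv(adm, paths$admissions, row.names = FALSE, quote = FALSE)
  utils::write.csv(grid, paths$grid, row.names = FALSE, quote = FALSE)
  utils::write.csv(xw, paths$crosswalk, row.names = FALSE, quote = FALSE)
  utils::write.csv(svi_tabs$area, paths$area_weights, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(svi_tabs$tract_svi, paths$tract_svi, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(unit_id = city_units), paths$city_units,
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(causes = unclass(causes)), paths$cause_map)
  yaml::write_yaml(list(
    surface = truth$surface,
    baseline = truth$baseline,
    weather = truth$weather,
    n_units = truth$n_units, n_cells = truth$n_cells,
    years = truth$years, start = format(truth$start),
    max_lag = truth$max_lag, seed = as.integer(seed)
  ), paths$truth)
  invisible(paths)
}

#' A small study truth calibrated to an expected case count
#'
#' Convenience constructor for the coverage and parameter-recovery
#' experiments: a compact geography (6 units, 4 cells, 2 years) with the
#' baseline log rate set so the expected total case count is roughly
#' `n_cases`. The baseline is season-free (`season_amplitude = 0`): unit
#' effects cancel exactly in the conditional likelihood, and removing
#' within-month baseline drift makes the within-stratum case-day
#' distribution follow the conditional-logistic form exactly, so these
#' truths measure the estimator itself rather than residual seasonal
#' confounding (which the full default truth retains).
#'
#' @param n_cases Target expected case count.
#' @param surface Surface list passed to [simulation_truth()].
#' @param ... Further arguments to [simulation_truth()].
#' @return A [simulation_truth()].
#' @export
calibration_truth <- function(n_cases, surface = list(family = "null"),
                              ...) {
  tr <- simulation_truth(n_units = 6L, n_cells = 4L, years = 2,
                         surface = surface,
                         baseline = list(unit_sd = 0.2,
                                         season_amplitude = 0),
                         ...)
  unit_days <- tr$n_units * (tr$n_days - tr$max_lag)
  cum_at_mean <- true_cumulative_logrr(tr, tr$weather$mean)
  tr$baseline$log_rate <- log(n_cases / unit_days) - cum_at_mean
  tr
}

#' Replicated coverage / parameter-recovery experiment
#'
#' For each replicate: simulates weather, builds the unit exposure table,
#' draws admissions from the truth's surface, runs them through
#' exclusions, classification and stratum construction, fits the
#' temperature cross-basis conditional logistic model, and records the
#' cumulative contrast at a target temperature against the truth's
#' reference, its confidence interval, and whether the interval covers
#' the true cumulative log rate ratio.
#'
#' @param truth A [simulation_truth()] (see [calibration_truth()]).
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate r uses `seed + 1000 * r` offsets.
#' @param at Target temperature; `NULL` (default) uses each replicate's
#'   75th percentile of pooled lagged temperature.
#' @param var_df,lag_df Cross-basis degrees of freedom (defaults 3, 4).
#' @param level CI coverage (default 0.95).
#' @return Data frame with one row per replicate: `estimate`, `se`,
#'   `ci_low`, `ci_high`, `true`, `covered`, `n_cases`, `at`.
#' @export
coverage_experiment <- function(truth, n_replicates, seed = 1L, at = NULL,
                                var_df = 3L, lag_df = 4L, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  # shared geography across replicates
  units <- sprintf("unit%03d", seq_len(truth$n_units))
  cells <- sprintf("cell%02d", seq_len(truth$n_cells))
  xw <- with_seed(seed, {
    do.call(rbind, lapply(units, function(u) {
      k <- sample(1:2, 1L)
      cs <- sample(cells, k)
      w <- stats::runif(k)
      data.frame(unit_id = u, cell_id = cs, weight = w / sum(w),
                 stringsAsFactors = FALSE)
    }))
  })
  tracts <- paste0("t", units)
  svi <- assign_svi_tertiles(
    data.frame(tract_id = tracts,
               svi_value = seq(0, 1, length.out = length(units))),
    data.frame(tract_id = tracts, unit_id = units, weight = 1))
  causes <- example_cause_map()

  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- seed + 1000L * r
    grid <- simulate_weather(truth, s)
    exposure <- build_exposure_table(grid, xw)
    adm <- simulate_admissions(truth, exposure, causes, seed = s + 1L)
    excl <- apply_exclusions(adm)
    classification <- classify_admissions(excl$records, causes)
    events <- extract_case_series(excl$records, names(causes)[1L],
                                  classification, svi)
    strata <- suppressMessages(build_strata(events, exposure, truth$max_lag))
    m <- fit_dlnm(strata, var_df = var_df, lag_df = lag_df,
                  include_rh = FALSE,
                  reference = truth$surface$reference)
    at_r <- if (is.null(at)) {
      as.numeric(stats::quantile(strata$lag_temperature, 0.75))
    } else at
    cc <- cumulative_contrast(
      m$fit$coefficients[m$idx_temperature],
      m$fit$vcov[m$idx_temperature, m$idx_temperature, drop = FALSE],
      m$spec_temperature, at_r)
    se <- sqrt(cc$variance)
    truev <- true_cumulative_logrr(truth, at_r)
    out[[r]] <- data.frame(
      estimate = cc$estimate, se = se,
      ci_low = cc$estimate - z * se, ci_high = cc$estimate + z * se,
      true = truev,
      covered = (cc$estimate - z * se) <= truev &
        truev <= (cc$estimate + z * se),
      converged = m$fit$converged,
      n_cases = nrow(strata$events), at = at_r)
  }
  do.call(rbind, out)
}
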