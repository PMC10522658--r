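#' Percent change in visit rates from a log rate ratio
#'
#' Converts a cumulative log rate ratio and its delta-method variance to
#' a percent change with a Wald confidence interval:
#' point = `100 (exp(eta) - 1)`, CI = `100 (exp(eta +/- z sd) - 1)`.
#'
#' @param eta Log rate ratio(s).
#' @param var Variance(s), `>= 0`; recycled against `eta`.
#' @param level Coverage (default 0.95).
#' @return Data frame `percent_change`, `ci_low`, `ci_high`.
#' @export
percent_change <- function(eta, var, level = 0.95) {
  if (any(var < 0)) stop("variance must be >= 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd <- sqrt(var)
  data.frame(
    percent_change = 100 * (exp(eta) - 1),
    ci_low = 100 * (exp(eta - z * sd) - 1),
    ci_high = 100 * (exp(eta + z * sd) - 1)
  )
}

#' Empirical temperature percentiles with Fahrenheit equivalents
#'
#' Linear-interpolation quantiles of an exposure distribution, reported
#' in degrees Celsius and Fahrenheit (F rounded to one decimal, the
#' convention of the tables these feed).
#'
#' @param values Numeric temperatures (deg C); e.g. the pooled lagged
#'   case+control exposures, or case-day exposures.
#' @param probs Probabilities (default 0.50, 0.75, 0.90, 0.99).
#' @return Data frame `prob`, `celsius`, `fahrenheit`.
#' @export
temperature_percentiles <- function(values,
                                    probs = c(0.50, 0.75, 0.90, 0.99)) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values supplied", call. = FALSE)
  cels <- as.numeric(stats::quantile(values, probs, names = FALSE, type = 7))
  data.frame(prob = probs, celsius = cels,
             fahrenheit = celsius_to_fahrenheit(cels))
}

#' @rdname temperature_percentiles
#' @param celsius Temperatures in deg C.
#' @export
celsius_to_fahrenheit <- function(celsius) {
  round(celsius * 9 / 5 + 32, 1)
}

#' Cumulative exposure-response curve with percentile contrasts
#'
#' Evaluates the fitted cumulative percent change (versus the spec's
#' reference temperature) over an equally spaced temperature grid and at
#' named exposure percentiles, with delta-method confidence intervals.
#' The curve passes exactly through zero (with a zero-width interval) at
#' the reference.
#'
#' @param fit A `clr_fit`.
#' @param spec The temperature [cross_basis_spec()] used in the fit.
#' @param coef_index Columns of `fit$coefficients` holding the
#'   temperature cross-basis block.
#' @param exposure_values Temperatures defining the grid range and the
#'   percentile contrasts (typically pooled lagged case+control values).
#' @param lags Lag subset to accumulate over (default all).
#' @param n_grid Number of grid points (default 100).
#' @param probs Percentiles to report (default 0.50, 0.75, 0.90, 0.99).
#' @param level CI coverage (default 0.95).
#' @return List of class `curve_table`: `curve` (data frame over the
#'   grid), `percentiles` (data frame of named contrasts), `reference`.
#' @export
curve_table <- function(fit, spec, coef_index, exposure_values,
                        lags = 0:spec$max_lag, n_grid = 100L,
                        probs = c(0.50, 0.75, 0.90, 0.99), level = 0.95) {
  theta <- fit$coefficients[coef_index]
  Sigma <- fit$vcov[coef_index, coef_index, drop = FALSE]
  rng <- range(exposure_values[is.finite(exposure_values)])
  grid <- seq(rng[1L], rng[2L], length.out = n_grid)

  eval_at <- function(at) {
    cc <- cumulative_contrast(theta, Sigma, spec, at, lags)
    cbind(at_temperature = at,
          eta = cc$estimate, variance = cc$variance,
          percent_change(cc$estimate, cc$variance, level))
  }
  curve <- do.call(rbind, lapply(grid, eval_at))
  pct <- temperature_percentiles(exposure_values, probs)
  pctc <- do.call(rbind, lapply(pct$celsius, eval_at))
  pctc <- cbind(prob = pct$prob, fahrenheit = pct$fahrenheit, pctc)
  structure(list(curve = curve, percentiles = pctc,
                 reference = spec$reference,
                 lags = lags, level = level),
            class = "curve_table")
}

#' @export
print.curve_table <- function(x, ...) {
  cat(sprintf(
    "cumulative exposure-response curve: %d grid points, reference %.1f C, lags %s\n",
    nrow(x$curve), x$reference, paste(range(x$lags), collapse = "-")))
  print(x$percentiles, row.names = FALSE)
  invisible(x)
}

#' Compare two matched sets of effect estimates
#'
#' Sensitivity-analysis summary: Pearson correlation between matched
#' point estimates, and the least-squares slope of the alternative
#' estimates on the main ones with a normal-theory confidence interval.
#' Identical sets give R = 1 and slope 1.
#'
#' @param estimates_main,estimates_alt Numeric vectors of matched point
#'   estimates (same cause/stratum/temperature points, same order).
#' @param level CI coverage (default 0.95).
#' @return List `r`, `slope`, `slope_ci` (length 2).
#' @export
sensitivity_compare <- function(estimates_main, estimates_alt,
                                level = 0.95) {
  if (length(estimates_main) != length(estimates_alt)) {
    stop("estimate sets have different lengths", call. = FALSE)
  }
  r <- stats::cor(estimates_main, estimates_alt)
  fit <- stats::lm(estimates_alt ~ estimates_main)
  slope <- unname(stats::coef(fit)[2L])
  ci <- suppressWarnings(stats::confint(fit, "estimates_main",
                                        level = level))
  list(r = r, slope = slope, slope_ci = as.numeric(ci))
}

#' Run the full case-crossover DLNM analysis
#'
#' End-to-end driver: ingests exposure and cohort inputs, applies
#' exclusions, classifies causes, builds time-stratified strata with
#' lagged exposures, selects (or fixes) spline degrees of freedom,
#' fits the conditional logistic DLNM with temperature and
#' relative-humidity cross-bases, and emits cumulative
#' exposure-response curve tables for the overall analysis and for each
#' stratified analysis (location, sex, age group, SVI tertile), plus the
#' lag 0-1 secondary fit and the no-humidity sensitivity comparison.
#'
#' `config` is a list (or path to a YAML file) with elements:
#' \describe{
#'   \item{admissions, grid, crosswalk, area_weights, tract_svi}{data
#'     frames, or file paths read with the package readers}
#'   \item{cause_map}{a [cause_map()], list, or YAML path}
#'   \item{city_units}{character vector of in-city unit ids (optional)}
#'   \item{causes}{cause names to analyze (default: all in the map)}
#'   \item{period}{length-2 date range (optional)}
#'   \item{max_lag}{default 6}
#'   \item{var_df, lag_df}{fixed degrees of freedom; when omitted the
#'     AIC grid (`var_df_grid` x `lag_df_grid`, defaults {3,4} x {2..5})
#'     is searched per cause}
#'   \item{reference}{reference temperature; default the minimum
#'     observed daily exposure over the period}
#'   \item{percentiles}{probabilities for named contrasts}
#'   \item{percentile_source}{"case_control" (default: pooled lagged
#'     case+control exposures) or "case" (case-day lag-0 values)}
#'   \item{stratified}{run the four stratified analyses (default TRUE)}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return List of class `cco_result`: per-cause results (`fit`,
#'   `df_selection`, `curves` per stratum label, `secondary` lag 0-1
#'   curve, `sensitivity`), the exposure table, the exclusion report and
#'   the configuration used.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get_tab <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) x else reader(x)
  }
  cmap <- config$cause_map
  if (is.character(cmap)) cmap <- read_cause_map(cmap)
  if (!inherits(cmap, "cause_map")) cmap <- cause_map(cmap)

  exposure <- get_tab(config$exposure, read_exposure_series)
  if (is.null(exposure)) {
    grid <- get_tab(config$grid, read_grid_series)
    xw <- get_tab(config$crosswalk, read_crosswalk)
    exposure <- build_exposure_table(grid, xw, config$period)
  }

  admissions <- get_tab(config$admissions, read_admissions)
  excl <- apply_exclusions(admissions, config$period)
  classification <- classify_admissions(excl$records, cmap)
  svi <- assign_svi_tertiles(get_tab(config$tract_svi, utils::read.csv),
                             get_tab(config$area_weights, utils::read.csv))
  city_units <- as.character(config$city_units %||% character())

  causes <- config$causes %||% names(cmap)
  max_lag <- config$max_lag %||% 6L
  probs <- config$percentiles %||% c(0.50, 0.75, 0.90, 0.99)
  pct_source <- config$percentile_source %||% "case_control"
  stratified <- config$stratified %||% TRUE
  level <- config$level %||% 0.95

  results <- list()
  for (cz in causes) {
    events <- extract_case_series(excl$records, cz, classification, svi,
                                  city_units)
    if (!nrow(events)) {
      warning(sprintf("cause '%s': no events; skipped", cz))
      next
    }
    strata <- build_strata(events, exposure, max_lag)
    reference <- config$reference %||% min(strata$lag_temperature)

    if (!is.null(config$var_df) && !is.null(config$lag_df)) {
      sel <- fit_dlnm(strata, config$var_df, config$lag_df,
                      reference = reference)
      sel$var_df <- config$var_df
      sel$lag_df <- config$lag_df
      sel$table <- NULL
      df_fixed <- TRUE
    } else {
      sel <- aic_grid_select(strata,
                             config$var_df_grid %||% c(3L, 4L),
                             config$lag_df_grid %||% 2:5,
                             reference = reference)
      df_fixed <- FALSE
    }

    pvals <- if (identical(pct_source, "case")) {
      strata$lag_temperature[strata$rows$is_case == 1L, 1L]
    } else {
      as.vector(strata$lag_temperature)
    }

    curves <- list(
      overall = curve_table(sel$fit, sel$spec_temperature,
                            sel$idx_temperature, pvals, probs = probs,
                            level = level))
    if (isTRUE(stratified)) {
      for (by in c("location_group", "sex", "age_group", "svi_tertile")) {
        for (lvl in sort(unique(strata$events[[by]]))) {
          sub <- subset_strata(strata, strata$events[[by]] == lvl)
          if (!nrow(sub$events)) next
          f <- tryCatch(
            fit_dlnm_with_specs(sub, sel$spec_temperature, sel$spec_rh),
            error = function(e) NULL)
          if (is.null(f) || !f$fit$converged) {
            warning(sprintf("cause '%s', stratum %s=%s: fit unavailable",
                            cz, by, lvl))
            next
          }
          curves[[paste(by, lvl, sep = ":")]] <-
            curve_table(f$fit, sel$spec_temperature, f$idx_temperature,
                        pvals, probs = probs, level = level)
        }
      }
    }

    # secondary analysis: lags 0-1 as a separate model with an
    # unconstrained (one column per lag) lag basis
    strata01 <- build_strata(events, exposure, max_lag = 1L)
    sec <- fit_dlnm(strata01, var_df = sel$var_df, lag_df = 2L,
                    lag_type = "identity", reference = reference)
    secondary <- curve_table(sec$fit, sec$spec_temperature,
                             sec$idx_temperature, pvals, probs = probs,
                             level = level)
    # the lag-subset contrast from the 0-6 fit is also available:
    secondary_subset <- curve_table(sel$fit, sel$spec_temperature,
                                    sel$idx_temperature, pvals,
                                    lags = 0:1, probs = probs,
                                    level = level)

    # sensitivity: same model without the relative-humidity terms
    alt <- fit_dlnm_with_specs(strata, sel$spec_temperature, NULL)
    alt_curve <- curve_table(alt$fit, sel$spec_temperature,
                             alt$idx_temperature, pvals, probs = probs,
                             level = level)
    sens <- sensitivity_compare(curves$overall$curve$percent_change,
                                alt_curve$curve$percent_change)

    results[[cz]] <- list(
      cause = cz,
      n_events = nrow(strata$events),
      n_dropped = strata$n_dropped,
      var_df = sel$var_df, lag_df = sel$lag_df, df_fixed = df_fixed,
      aic_table = sel$table,
      fit = sel$fit,
      spec_temperature = sel$spec_temperature,
      spec_rh = sel$spec_rh,
      reference = reference,
      curves = curves,
      secondary = secondary,
      secondary_subset = secondary_subset,
      sensitivity = c(sens, list(curve_no_rh = alt_curve))
    )
  }
  structure(list(causes = results,
                 exposure = exposure,
                 exclusions = excl$report,
                 svi = svi,
                 config = config),
            class = "cco_result")
}

# refit with frozen cross-basis specs (used for stratified analyses and
# the no-humidity sensitivity model, so all runs share one basis)
fit_dlnm_with_specs <- function(strata, spec_t, spec_r) {
  cb_t <- cross_basis(strata$lag_temperature, spec_t)
  colnames(cb_t) <- paste0("T.", colnames(cb_t))
  if (!is.null(spec_r)) {
    cb_r <- cross_basis(strata$lag_rh, spec_r)
    colnames(cb_r) <- paste0("RH.", colnames(cb_r))
    data <- clr_design(strata, cb_t, cb_r)
  } else {
    data <- clr_design(strata, cb_t)
  }
  fit <- fit_clr(data)
  kt <- ncol(cb_t)
  list(fit = fit, data = data,
       idx_temperature = seq_len(kt),
       idx_rh = if (!is.null(spec_r)) kt + seq_len(kt) else integer())
}

#' @export
print.cco_result <- function(x, ...) {
  cat(sprintf("case-crossover DLNM analysis: %d cause(s)\n",
              length(x$causes)))
  for (res in x$causes) {
    cat(sprintf(
      "  %s: %d events, df_var=%d df_lag=%d%s, AIC %.1f\n",
      res$cause, res$n_events, res$var_df, res$lag_df,
      if (res$df_fixed) " (fixed)" else " (AIC-selected)", res$fit$aic))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
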