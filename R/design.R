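#' Time-stratified control days for a case day
#'
#' Control days are every other day in the same calendar month and year
#' sharing the case day's day of week, in ascending order. Matching on
#' (year, month, weekday) controls season, long-term trend and weekday
#' patterns by design; a month contributes 2-4 controls depending on how
#' often the weekday occurs.
#'
#' @param case_date A single date (or string coercible to `Date`).
#' @return `Date` vector of control days (the case day is never included).
#' @examples
#' control_days("2010-07-14")  # Wednesdays of July 2010 except the 14th
#' @export
control_days <- function(case_date) {
  d <- as_date_strict(case_date)
  stopifnot(length(d) == 1L, !is.na(d))
  first <- as.Date(format(d, "%Y-%m-01"))
  last <- seq(first, by = "month", length.out = 2L)[2L] - 1L
  month_days <- seq(first, last, by = "day")
  out <- month_days[iso_weekday(month_days) == iso_weekday(d) &
                      month_days != d]
  out
}

#' Build matched case-crossover strata with lagged exposures
#'
#' For each case event, forms the stratum of its case day plus its
#' time-stratified control days, and attaches lag-0..`max_lag` daily
#' temperature and relative humidity for every day in the stratum. Events
#' whose stratum (including the lag window of its earliest day) is not
#' fully covered by the exposure series for their unit are dropped with a
#' message; a gap inside the covered range is an error.
#'
#' @param events Case-event data frame (see [extract_case_series()]); only
#'   `admission_date` and `unit_id` are required, other columns are
#'   carried along for stratified analyses.
#' @param exposure Unit-level exposure series from
#'   [build_exposure_table()] (columns `unit_id`, `date`, `temperature`,
#'   `relative_humidity`).
#' @param max_lag Maximum exposure lag in days (default 6). With
#'   same-weekday referents 7 days apart, lags 0-6 guarantee that case
#'   and control lag windows never overlap.
#' @return Object of class `cco_strata`: a list with `rows` (data frame
#'   `stratum_id`, `unit_id`, `date`, `is_case`), `lag_temperature` and
#'   `lag_rh` (row-aligned matrices with `max_lag + 1` columns, lag 0
#'   first), `events` (the retained events), `max_lag` and `n_dropped`.
#' @export
build_strata <- function(events, exposure, max_lag = 6L) {
  stopifnot(max_lag >= 0L)
  ev_date <- as_date_strict(events$admission_date)
  ev_unit <- as.character(events$unit_id)
  n_ev <- length(ev_date)
  if (n_ev == 0L) stop("no events supplied", call. = FALSE)

  # per-unit contiguous exposure vectors, concatenated with offsets for O(1)
  # vectorized lookup by (unit, day)
  exposure$date <- as_date_strict(exposure$date)
  units <- sort(unique(ev_unit))
  missing_units <- setdiff(units, unique(exposure$unit_id))
  if (length(missing_units)) {
    stop("exposure missing for unit(s): ",
         paste(missing_units, collapse = ", "), call. = FALSE)
  }
  ex <- exposure[exposure$unit_id %in% units, , drop = FALSE]
  ex <- ex[order(ex$unit_id, ex$date), , drop = FALSE]
  idx_by_unit <- split(seq_len(nrow(ex)), ex$unit_id)
  start_day <- vapply(idx_by_unit, function(ix) as.integer(ex$date[ix[1L]]),
                      0L)
  len <- lengths(idx_by_unit)
  for (u in names(idx_by_unit)) {
    ix <- idx_by_unit[[u]]
    dd <- as.integer(ex$date[ix])
    if (length(dd) > 1L && any(diff(dd) != 1L)) {
      gap <- dd[which(diff(dd) != 1L)[1L]] + 1L
      stop(sprintf("exposure gap for unit '%s' at %s", u,
                   as.Date(gap, origin = "1970-01-01")), call. = FALSE)
    }
  }
  end_day <- start_day + len - 1L
  offset <- cumsum(c(0L, len[-length(len)]))
  names(offset) <- names(idx_by_unit)
  big_t <- ex$temperature[unlist(idx_by_unit, use.names = FALSE)]
  big_r <- ex$relative_humidity[unlist(idx_by_unit, use.names = FALSE)]

  # vectorized same-weekday referent enumeration (proleptic Gregorian,
  # civil dates): candidate days of month are d0, d0+7, ..., where d0 is
  # the first occurrence of the case weekday in the month
  lt <- as.POSIXlt(ev_date)
  yr <- lt$year + 1900L
  mo <- lt$mon + 1L
  mday <- lt$mday
  month_first <- as.integer(ev_date) - (mday - 1L)
  dim_tab <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  nd <- dim_tab[mo]
  leap <- (yr %% 4L == 0L) & (yr %% 100L != 0L | yr %% 400L == 0L)
  nd[mo == 2L & leap] <- 29L
  d0 <- 1L + ((mday - 1L) %% 7L)
  cand <- outer(d0, 7L * (0:4), `+`)        # n_ev x 5 days of month
  valid <- cand <= nd
  is_ctrl <- valid & cand != mday
  n_ctrl <- rowSums(is_ctrl)
  n_occ <- rowSums(valid)

  # coverage: earliest stratum day minus max_lag, and latest stratum day,
  # must lie in the unit's exposure window
  strat_min <- month_first + d0 - 1L
  strat_max <- month_first + d0 + 7L * (n_occ - 1L) - 1L
  u_start <- start_day[ev_unit]
  u_end <- end_day[ev_unit]
  keep <- (strat_min - max_lag) >= u_start & strat_max <= u_end
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(sprintf(
      "build_strata: dropped %d event(s) without full exposure coverage",
      n_dropped))
  }
  if (!any(keep)) stop("no events with full exposure coverage", call. = FALSE)

  kev <- which(keep)
  n_rows_per <- (n_ctrl + 1L)[kev]
  stratum_id <- rep(seq_along(kev), n_rows_per)
  row_unit <- rep(ev_unit[kev], n_rows_per)
  is_case <- as.integer(sequence(n_rows_per) == 1L)
  # within each stratum: case day first, then controls ascending
  ctrl_mday <- t(cand[kev, , drop = FALSE])[t(is_ctrl[kev, , drop = FALSE])]
  row_day <- integer(length(stratum_id))
  row_day[is_case == 1L] <- as.integer(ev_date)[kev]
  row_day[is_case == 0L] <- rep(month_first[kev], n_rows_per - 1L) +
    ctrl_mday - 1L
  row_date <- as.Date(row_day, origin = "1970-01-01")

  n <- length(row_date)
  gidx0 <- offset[row_unit] + (as.integer(row_date) - start_day[row_unit]) + 1L
  lag_t <- matrix(NA_real_, n, max_lag + 1L)
  lag_r <- lag_t
  for (l in 0:max_lag) {
    lag_t[, l + 1L] <- big_t[gidx0 - l]
    lag_r[, l + 1L] <- big_r[gidx0 - l]
  }
  if (anyNA(lag_t) || anyNA(lag_r)) {
    bad <- which(rowSums(is.na(lag_t)) > 0)[1L]
    stop(sprintf("missing exposure for unit '%s' near %s",
                 row_unit[bad], row_date[bad]), call. = FALSE)
  }
  colnames(lag_t) <- colnames(lag_r) <- paste0("lag", 0:max_lag)

  structure(list(
    rows = data.frame(stratum_id = stratum_id, unit_id = row_unit,
                      date = row_date, is_case = is_case,
                      stringsAsFactors = FALSE),
    lag_temperature = lag_t,
    lag_rh = lag_r,
    events = events[kev, , drop = FALSE],
    max_lag = as.integer(max_lag),
    n_dropped = n_dropped
  ), class = "cco_strata")
}

#' @export
print.cco_strata <- function(x, ...) {
  cat(sprintf(
    "case-crossover strata: %d strata, %d rows, lags 0-%d (%d dropped)\n",
    max(x$rows$stratum_id), nrow(x$rows), x$max_lag, x$n_dropped))
  invisible(x)
}

#' Subset strata by a predicate on their events
#'
#' Keeps the strata whose generating event satisfies `keep`, renumbering
#' stratum ids consecutively. Used for stratified analyses (by sex, age
#' group, location, SVI tertile), which partition the stratum set.
#'
#' @param strata A `cco_strata` object.
#' @param keep Logical vector, one element per stratum/event.
#' @return A `cco_strata` object.
#' @export
subset_strata <- function(strata, keep) {
  stopifnot(inherits(strata, "cco_strata"),
            length(keep) == nrow(strata$events))
  keep[is.na(keep)] <- FALSE
  sid <- strata$rows$stratum_id
  row_keep <- keep[sid]
  new_id <- cumsum(keep)
  rows <- strata$rows[row_keep, , drop = FALSE]
  rows$stratum_id <- new_id[sid[row_keep]]
  rownames(rows) <- NULL
  structure(list(
    rows = rows,
    lag_temperature = strata$lag_temperature[row_keep, , drop = FALSE],
    lag_rh = strata$lag_rh[row_keep, , drop = FALSE],
    events = strata$events[keep, , drop = FALSE],
    max_lag = strata$max_lag,
    n_dropped = strata$n_dropped
  ), class = "cco_strata")
}

#' Serialize strata to a long audit table
#'
#' One row per (stratum row, lag): `stratum_id`, `date`, `is_case`, `lag`,
#' `temperature`, `relative_humidity`.
#'
#' @param strata A `cco_strata` object.
#' @param path Optional path; when given the table is written as CSV.
#' @return The long-format data frame (invisibly when `path` is given).
#' @export
strata_long <- function(strata, path = NULL) {
  L <- strata$max_lag
  n <- nrow(strata$rows)
  out <- data.frame(
    stratum_id = rep(strata$rows$stratum_id, each = L + 1L),
    date = rep(strata$rows$date, each = L + 1L),
    is_case = rep(strata$rows$is_case, each = L + 1L),
    lag = rep(0:L, times = n),
    temperature = as.vector(t(strata$lag_temperature)),
    relative_humidity = as.vector(t(strata$lag_rh))
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
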