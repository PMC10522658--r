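#' Validate a gridded daily weather table
#'
#' A grid series is a long-format data frame with one row per grid cell and
#' calendar day, columns `cell_id`, `date`, `temperature` (deg C),
#' `specific_humidity` (kg/kg) and `pressure` (hPa). Dates must be
#' contiguous within each cell.
#'
#' @param grid Data frame as described above; `date` coercible to `Date`.
#' @return The validated data frame, with `date` as class `Date`,
#'   invisibly usable downstream.
#' @export
validate_grid_series <- function(grid) {
  need <- c("cell_id", "date", "temperature", "specific_humidity", "pressure")
  miss <- setdiff(need, names(grid))
  if (length(miss)) {
    stop("grid series missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grid$date <- as_date_strict(grid$date)
  if (anyNA(grid$date)) stop("unparseable dates in grid series", call. = FALSE)
  check_finite(grid$temperature, "temperature")
  check_finite(grid$specific_humidity, "specific_humidity")
  check_finite(grid$pressure, "pressure")
  if (any(grid$specific_humidity < 0)) {
    stop("specific_humidity must be >= 0", call. = FALSE)
  }
  if (any(grid$pressure <= 0)) stop("pressure must be > 0", call. = FALSE)
  key <- paste(grid$cell_id, grid$date)
  if (anyDuplicated(key)) {
    stop("duplicate (cell_id, date) rows in grid series", call. = FALSE)
  }
  for (cell in unique(grid$cell_id)) {
    d <- sort(grid$date[grid$cell_id == cell])
    gap <- which(diff(as.integer(d)) != 1L)
    if (length(gap)) {
      stop(sprintf("calendar gap in grid series: cell '%s' missing %s",
                   cell, d[gap[1L]] + 1L), call. = FALSE)
    }
  }
  grid
}

#' Validate a cell-to-unit population-weight crosswalk
#'
#' @param weights Data frame with columns `unit_id`, `cell_id`, `weight`.
#'   Weights must be non-negative and sum to 1 within each unit
#'   (tolerance 1e-9).
#' @return The validated data frame.
#' @export
validate_crosswalk <- function(weights) {
  need <- c("unit_id", "cell_id", "weight")
  miss <- setdiff(need, names(weights))
  if (length(miss)) {
    stop("crosswalk missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_finite(weights$weight, "weight")
  if (any(weights$weight < 0)) stop("weights must be >= 0", call. = FALSE)
  sums <- rowsum(weights$weight, weights$unit_id)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    stop("crosswalk weights do not sum to 1 for unit(s): ",
         paste(rownames(sums)[off], collapse = ", "), call. = FALSE)
  }
  weights
}

#' Population-weighted aggregation of per-cell values to units
#'
#' Computes, for each unit, the convex combination
#' \eqn{\sum_{cells} w_{uc} x_c} of the per-cell values for a single day.
#'
#' @param grid_values Named numeric vector of per-cell values; names are
#'   cell ids.
#' @param weights Crosswalk data frame (`unit_id`, `cell_id`, `weight`).
#' @return Named numeric vector, one value per unit id.
#' @export
population_weight_to_units <- function(grid_values, weights) {
  missing_cells <- setdiff(unique(weights$cell_id), names(grid_values))
  if (length(missing_cells)) {
    stop("cells referenced by crosswalk absent from grid values: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  v <- grid_values[match(weights$cell_id, names(grid_values))]
  agg <- rowsum(weights$weight * as.numeric(v), weights$unit_id)
  named(drop(agg), rownames(agg))
}

#' Build a unit-level daily exposure table from gridded weather
#'
#' Derives relative humidity at the grid-cell level (RH is non-linear in
#' its inputs, so it is computed before any spatial averaging), then
#' population-weights temperature and relative humidity to the unit
#' (ZIP/ZCTA) level for every day of the period.
#'
#' @param grid Grid series data frame (see [validate_grid_series()]).
#' @param weights Cell-to-unit crosswalk (see [validate_crosswalk()]).
#' @param period Length-2 `Date` (or coercible) vector giving the first and
#'   last day; defaults to the full date range of `grid`.
#' @return Data frame with columns `unit_id`, `date`, `temperature`,
#'   `relative_humidity`; exactly one row per (unit, day).
#' @export
build_exposure_table <- function(grid, weights, period = NULL) {
  grid <- validate_grid_series(grid)
  weights <- validate_crosswalk(weights)
  if (is.null(period)) period <- range(grid$date)
  period <- as_date_strict(period)
  days <- seq(period[1L], period[2L], by = "day")

  cells <- sort(unique(weights$cell_id))
  g <- grid[grid$cell_id %in% cells &
              grid$date >= period[1L] & grid$date <= period[2L], , drop = FALSE]
  i <- match(g$cell_id, cells)
  j <- match(g$date, days)

  tm <- matrix(NA_real_, length(cells), length(days))
  rh <- tm
  tm[cbind(i, j)] <- g$temperature
  rh[cbind(i, j)] <- relative_humidity(g$temperature, g$specific_humidity,
                                       g$pressure)
  if (anyNA(tm)) {
    hole <- which(is.na(tm), arr.ind = TRUE)[1L, ]
    stop(sprintf("grid does not cover period: cell '%s' missing %s",
                 cells[hole[1L]], days[hole[2L]]), call. = FALSE)
  }

  units <- sort(unique(weights$unit_id))
  w <- matrix(0, length(units), length(cells),
              dimnames = list(units, cells))
  w[cbind(match(weights$unit_id, units), match(weights$cell_id, cells))] <-
    weights$weight

  ut <- w %*% tm  # units x days
  ur <- w %*% rh

  data.frame(
    unit_id = rep(units, times = length(days)),
    date = rep(days, each = length(units)),
    temperature = as.vector(ut),
    relative_humidity = as.vector(ur),
    stringsAsFactors = FALSE
  )
}

#' Read / write exposure and grid tables
#'
#' Thin delimited-text readers and writers for the standard long formats:
#' grid series (`cell_id,date,temperature,specific_humidity,pressure`),
#' exposure series (`unit_id,date,temperature,relative_humidity`) and
#' crosswalks (`unit_id,cell_id,weight`). Dates are ISO-8601.
#'
#' @param path File path.
#' @return A validated data frame.
#' @name exposure_io
NULL

#' @rdname exposure_io
#' @export
read_grid_series <- function(path) {
  validate_grid_series(utils::read.csv(path, stringsAsFactors = FALSE,
                                       colClasses = c(cell_id = "character")))
}

#' @rdname exposure_io
#' @export
read_crosswalk <- function(path) {
  validate_crosswalk(utils::read.csv(path, stringsAsFactors = FALSE,
                                     colClasses = c(unit_id = "character",
                                                    cell_id = "character")))
}

#' @rdname exposure_io
#' @export
read_exposure_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(unit_id = "character"))
  x$date <- as_date_strict(x$date)
  if (any(x$relative_humidity < 0 | x$relative_humidity > 100)) {
    stop("relative_humidity outside [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(paste(x$unit_id, x$date))) {
    stop("duplicate (unit_id, date) rows in exposure series", call. = FALSE)
  }
  x
}

#' @rdname exposure_io
#' @param x Table to write.
#' @export
write_exposure_series <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
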