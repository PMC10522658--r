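#' Relative humidity from temperature, specific humidity and pressure
#'
#' Converts specific humidity to relative humidity using the actual vapor
#' pressure implied by the mixing state of the air,
#' \eqn{e = q p / (0.622 + 0.378 q)}, and the Magnus approximation to the
#' saturation vapor pressure over water,
#' \eqn{e_s = 6.112 \exp(17.67 T / (T + 243.5))} hPa.
#' The result \eqn{100 \, e / e_s} is clipped to \eqn{[0, 100]}.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param temperature Daily mean air temperature, degrees Celsius.
#' @param specific_humidity Specific humidity, kg water vapor per kg air;
#'   must be non-negative.
#' @param pressure Surface pressure, hPa; must be strictly positive.
#'
#' @return Numeric vector of relative humidity in percent, in \eqn{[0, 100]}.
#'
#' @examples
#' relative_humidity(20, 0.00728, 1013.25)
#' relative_humidity(15, 0, 1000)          # dry air -> 0
#' @export
relative_humidity <- function(temperature, specific_humidity, pressure) {
  check_finite(temperature, "temperature")
  check_finite(specific_humidity, "specific_humidity")
  check_finite(pressure, "pressure")
  if (any(pressure <= 0)) {
    stop("'pressure' must be strictly positive (hPa)", call. = FALSE)
  }
  if (any(specific_humidity < 0)) {
    stop("'specific_humidity' must be non-negative (kg/kg)", call. = FALSE)
  }
  e <- specific_humidity * pressure / (0.622 + 0.378 * specific_humidity)
  es <- 6.112 * exp(17.67 * temperature / (temperature + 243.5))
  pmin(pmax(100 * e / es, 0), 100)
}

#' Specific humidity reproducing a target relative humidity
#'
#' Inverse of [relative_humidity()] at fixed temperature and pressure:
#' returns the specific humidity q such that the derived relative humidity
#' equals `rh`. Used by the weather simulator so that downstream RH values
#' land in a controlled range by construction.
#'
#' @param rh Relative humidity, percent.
#' @param temperature Degrees Celsius.
#' @param pressure hPa.
#' @return Specific humidity, kg/kg.
#' @export
specific_humidity_for_rh <- function(rh, temperature, pressure) {
  es <- 6.112 * exp(17.67 * temperature / (temperature + 243.5))
  e <- rh / 100 * es
  0.622 * e / (pressure - 0.378 * e)
}
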