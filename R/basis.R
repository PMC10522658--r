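#' Natural cubic spline specification
#'
#' A spline spec fixes the degrees of freedom, interior knots and boundary
#' knots of a natural cubic spline basis (no intercept column; linear
#' beyond the boundary knots), so the same basis functions can be
#' re-evaluated at arbitrary points, e.g. at prediction time.
#'
#' @param df Degrees of freedom (number of basis columns), >= 1.
#' @param boundary_knots Length-2 numeric, lower and upper boundary.
#' @param interior_knots Ordered numeric of length `df - 1`, strictly
#'   inside the boundary; `NULL` for `df = 1` (a single linear column).
#' @return Object of class `spline_spec`.
#' @export
spline_spec <- function(df, boundary_knots, interior_knots = NULL) {
  df <- as.integer(df)
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  interior_knots <- as.numeric(interior_knots)
  if (length(interior_knots) != df - 1L) {
    stop(sprintf("df = %d requires %d interior knot(s), got %d",
                 df, df - 1L, length(interior_knots)), call. = FALSE)
  }
  if (anyDuplicated(c(boundary_knots, interior_knots))) {
    stop("degenerate (duplicated) knots", call. = FALSE)
  }
  if (length(interior_knots) &&
      (any(interior_knots <= boundary_knots[1L]) ||
       any(interior_knots >= boundary_knots[2L]))) {
    stop("interior knots must lie strictly inside the boundary knots",
         call. = FALSE)
  }
  structure(list(df = df,
                 interior_knots = sort(interior_knots),
                 boundary_knots = as.numeric(sort(boundary_knots))),
            class = "spline_spec")
}

#' Spline spec with knots at equally spaced percentiles
#'
#' The conventional DLNM placement for the exposure dimension: interior
#' knots at the `i/df` quantiles (e.g. `df = 3` puts knots at the 33.3rd
#' and 66.7th percentiles), boundary knots at the observed minimum and
#' maximum.
#'
#' @param x Observed exposure values (typically the pooled case + control
#'   lagged exposures).
#' @param df Degrees of freedom.
#' @return A [spline_spec()].
#' @export
var_spline_spec <- function(x, df) {
  x <- x[is.finite(x)]
  probs <- seq_len(df - 1L) / df
  ik <- if (df > 1L) as.numeric(stats::quantile(x, probs, names = FALSE))
        else NULL
  spline_spec(df, range(x), ik)
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the `df` natural cubic spline basis functions defined by
#' `spec` at arbitrary `x`, including points beyond the boundary knots
#' (where every basis function continues linearly).
#'
#' @param x Numeric values.
#' @param spec A [spline_spec()].
#' @return `length(x) x df` matrix.
#' @export
natural_spline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  b <- splines::ns(x,
                   knots = if (length(spec$interior_knots))
                     spec$interior_knots else NULL,
                   Boundary.knots = spec$boundary_knots,
                   intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(x), ncol = spec$df)
  colnames(m) <- paste0("v", seq_len(spec$df))
  m
}

#' Lag-basis matrix for a distributed-lag model
#'
#' Returns the `(max_lag + 1) x df_lag` matrix of lag-basis functions
#' evaluated at lags `0..max_lag`. The default (`type = "ns"`) is the
#' conventional DLNM lag structure: a constant (intercept) column plus a
#' natural cubic spline in `log(lag + 1)` with interior knots equally
#' spaced on the log-lag scale (`df_lag = 4` gives 2 interior knots).
#' `type = "identity"` gives one indicator column per lag (an
#' unconstrained lag structure, used e.g. for a lag 0-1 model), where
#' `df_lag` is forced to `max_lag + 1`.
#'
#' @param max_lag Maximum lag in days.
#' @param df_lag Degrees of freedom along the lag dimension.
#' @param type `"ns"` or `"identity"`.
#' @return Matrix with lags as rows (lag 0 first) and basis columns.
#' @export
lag_basis <- function(max_lag, df_lag, type = c("ns", "identity")) {
  type <- match.arg(type)
  lags <- 0:max_lag
  if (type == "identity") {
    m <- diag(max_lag + 1L)
    colnames(m) <- paste0("l", lags)
    return(m)
  }
  df_lag <- as.integer(df_lag)
  if (df_lag < 1L) stop("df_lag must be >= 1", call. = FALSE)
  if (df_lag > max_lag + 1L) {
    stop("df_lag cannot exceed max_lag + 1", call. = FALSE)
  }
  if (df_lag == 1L) {
    m <- matrix(1, max_lag + 1L, 1L)
  } else {
    lx <- log(lags + 1)
    bk <- range(lx)
    n_ik <- df_lag - 2L
    ik <- if (n_ik > 0L) {
      seq(bk[1L], bk[2L], length.out = n_ik + 2L)[-c(1L, n_ik + 2L)]
    } else NULL
    sp <- spline_spec(df_lag - 1L, bk, ik)
    m <- cbind(1, natural_spline_basis(lx, sp))
  }
  colnames(m) <- paste0("l", seq_len(ncol(m)))
  rownames(m) <- lags
  m
}

#' Cross-basis specification
#'
#' Fixes everything needed to expand a matrix of lagged exposures into a
#' tensor-product design block and to form contrasts from a fit: the
#' exposure-dimension spline, the lag-dimension basis, the maximum lag and
#' the reference exposure value against which cumulative contrasts are
#' centred.
#'
#' @param var_spec A [spline_spec()] for the exposure dimension.
#' @param max_lag Maximum lag (days).
#' @param lag_df Degrees of freedom along the lag dimension (ignored for
#'   `lag_type = "identity"`).
#' @param lag_type `"ns"` (default) or `"identity"`; see [lag_basis()].
#' @param reference Reference exposure value (same units as the exposure;
#'   finite).
#' @return Object of class `cross_basis_spec` with the realized lag-basis
#'   matrix in `$lag_matrix`.
#' @export
cross_basis_spec <- function(var_spec, max_lag, lag_df,
                             lag_type = c("ns", "identity"),
                             reference) {
  lag_type <- match.arg(lag_type)
  stopifnot(inherits(var_spec, "spline_spec"), max_lag >= 0)
  if (!is.finite(reference)) stop("reference must be finite", call. = FALSE)
  lm <- lag_basis(max_lag, if (lag_type == "identity") max_lag + 1L
                  else lag_df, type = lag_type)
  structure(list(var_spec = var_spec,
                 max_lag = as.integer(max_lag),
                 lag_df = ncol(lm),
                 lag_type = lag_type,
                 lag_matrix = lm,
                 reference = as.numeric(reference)),
            class = "cross_basis_spec")
}

#' Expand lagged exposures into a cross-basis design block
#'
#' Entry `(i, (j, k))` of the result is
#' \eqn{\sum_{l=0}^{L} v_j(x_{il}) \, L_k(l)}, where \eqn{v_j} are the
#' exposure-basis functions and \eqn{L_k} the lag-basis functions: the
#' tensor-product expansion through which a single coefficient vector
#' describes a smooth exposure-lag-response surface. Columns are ordered
#' with the lag index fastest (`v1.l1, v1.l2, ...`).
#'
#' @param lagged_exposure Numeric matrix, rows = observations, columns =
#'   lags 0..max_lag (so `max_lag + 1` columns).
#' @param spec A [cross_basis_spec()].
#' @return `nrow(lagged_exposure) x (df_var * df_lag)` matrix with the
#'   spec attached as attribute `"spec"`.
#' @export
cross_basis <- function(lagged_exposure, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  x <- as.matrix(lagged_exposure)
  if (ncol(x) != spec$max_lag + 1L) {
    stop(sprintf("lagged exposure must have %d columns (lags 0-%d)",
                 spec$max_lag + 1L, spec$max_lag), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)[1L]
    stop(sprintf("non-finite exposure at row %d", bad), call. = FALSE)
  }
  dv <- spec$var_spec$df
  dl <- spec$lag_df
  n <- nrow(x)
  out <- matrix(0, n, dv * dl)
  jrep <- rep(seq_len(dv), each = dl)   # column (j,k): j-major, k fastest
  krep <- rep(seq_len(dl), times = dv)
  for (l in 0:spec$max_lag) {
    v <- natural_spline_basis(x[, l + 1L], spec$var_spec)
    w <- spec$lag_matrix[l + 1L, ]
    out <- out + v[, jrep, drop = FALSE] *
      matrix(w[krep], n, dv * dl, byrow = TRUE)
  }
  colnames(out) <- paste0("v", jrep, ".l", krep)
  attr(out, "spec") <- spec
  out
}

#' Cumulative contrast of a fitted exposure-lag-response surface
#'
#' For a fitted coefficient block `theta` on a cross-basis, computes the
#' cumulative log rate ratio of exposure `at` versus the spec's reference
#' value, summed over `lags`, together with its delta-method variance.
#' The gradient is
#' \eqn{g_{(j,k)} = [v_j(at) - v_j(ref)] \sum_{l \in lags} L_k(l)}, and
#' the returned quantities are \eqn{g^\top \theta} and
#' \eqn{g^\top \Sigma g}. Centring at prediction time (rather than
#' transforming the design) leaves the fitted likelihood untouched.
#'
#' @param theta Coefficient vector for this cross-basis block
#'   (length `df_var * df_lag`).
#' @param Sigma Covariance matrix of `theta` (same block).
#' @param spec The [cross_basis_spec()] used in the fit.
#' @param at Exposure value to contrast against the reference.
#' @param lags Integer subset of `0:max_lag` to accumulate over
#'   (default: all lags).
#' @return List with `estimate` (log rate ratio), `variance`, and the
#'   `gradient` vector.
#' @export
cumulative_contrast <- function(theta, Sigma, spec, at,
                                lags = 0:spec$max_lag) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  if (!is.finite(at)) stop("'at' must be finite", call. = FALSE)
  if (any(!(lags %in% 0:spec$max_lag))) {
    stop("lags outside 0..max_lag", call. = FALSE)
  }
  dv <- spec$var_spec$df
  dl <- spec$lag_df
  if (length(theta) != dv * dl) {
    stop("theta length does not match the cross-basis dimension",
         call. = FALSE)
  }
  vdiff <- natural_spline_basis(at, spec$var_spec) -
    natural_spline_basis(spec$reference, spec$var_spec)
  wsum <- colSums(spec$lag_matrix[lags + 1L, , drop = FALSE])
  g <- rep(as.numeric(vdiff), each = dl) * rep(wsum, times = dv)
  est <- sum(g * theta)
  v <- as.numeric(g %*% Sigma %*% g)
  list(estimate = est, variance = max(v, 0), gradient = g)
}
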