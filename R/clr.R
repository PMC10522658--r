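#' Assemble design data for conditional logistic fitting
#'
#' Binds one or more cross-basis blocks column-wise into the stratified
#' design used by the conditional logistic likelihood: a design matrix
#' `X`, a stratum index, and a case indicator (exactly one case per
#' stratum). Strata in which no covariate varies are non-informative
#' (they contribute a theta-free constant to the conditional likelihood)
#' and are dropped here with their count recorded.
#'
#' @param strata A `cco_strata` object.
#' @param ... One or more design blocks (matrices row-aligned with
#'   `strata$rows`, e.g. from [cross_basis()]).
#' @param drop_noninformative Drop strata whose rows are identical across
#'   all columns (default `TRUE`).
#' @return Object of class `clr_data`: list with `X`, `stratum`
#'   (integer), `is_case`, `groups` (row-index list per stratum) and
#'   `n_noninformative`.
#' @export
clr_design <- function(strata, ..., drop_noninformative = TRUE) {
  blocks <- list(...)
  stopifnot(length(blocks) >= 1L)
  X <- do.call(cbind, blocks)
  sid <- strata$rows$stratum_id
  is_case <- strata$rows$is_case
  stopifnot(nrow(X) == length(sid))

  ord <- order(sid)
  X <- X[ord, , drop = FALSE]
  sid <- sid[ord]
  is_case <- is_case[ord]
  groups <- split(seq_along(sid), sid)

  n_case <- vapply(groups, function(ix) sum(is_case[ix]), 0L)
  if (any(n_case != 1L)) {
    stop("every stratum must contain exactly one case row", call. = FALSE)
  }
  n_noninf <- 0L
  if (drop_noninformative) {
    # a stratum is informative iff some row differs from its first row
    gidx <- rep.int(seq_along(groups), lengths(groups))
    first_row <- vapply(groups, `[`, 0L, 1L)
    dev <- rowSums(abs(X - X[first_row[gidx], , drop = FALSE]))
    informative <- drop(rowsum(dev, gidx)) > 0
    n_noninf <- sum(!informative)
    if (n_noninf) {
      keep_rows <- unlist(groups[informative], use.names = FALSE)
      X <- X[keep_rows, , drop = FALSE]
      sid <- sid[keep_rows]
      is_case <- is_case[keep_rows]
      groups <- split(seq_along(sid), match(sid, unique(sid)))
      message(sprintf("clr_design: dropped %d non-informative stratum(-a)",
                      n_noninf))
    }
  }
  structure(list(X = X, stratum = sid, is_case = is_case,
                 groups = unname(groups), n_noninformative = n_noninf),
            class = "clr_data")
}


#' Stratified conditional logistic log-likelihood
#'
#' With one case per stratum the conditional likelihood contribution of
#' stratum c is the softmax probability of the case row:
#' \eqn{\ell(\theta) = \sum_c [x_{case}^\top\theta -
#' \log \sum_{r \in c} \exp(x_r^\top\theta)]}. Stratum-specific
#' intercepts cancel, so any covariate shift that is constant within a
#' stratum leaves the likelihood unchanged. The log-sum-exp is computed
#' with per-stratum max subtraction for numerical stability. Analytic
#' gradient and Hessian are returned for Newton-type optimization.
#'
#' @param theta Coefficient vector (length `ncol(data$X)`).
#' @param data A `clr_data` object from [clr_design()].
#' @return List with `loglik` (scalar), `gradient` and `hessian`
#'   (negative semi-definite; the likelihood is concave).
#' @export
conditional_loglik <- function(theta, data) {
  stopifnot(inherits(data, "clr_data"))
  X <- data$X
  if (length(theta) != ncol(X)) {
    stop(sprintf("theta has length %d but design has %d columns",
                 length(theta), ncol(X)), call. = FALSE)
  }
  eta <- drop(X %*% theta)
  gmax <- vapply(data$groups, function(ix) max(eta[ix]), 0)
  sid <- rep.int(seq_along(data$groups), lengths(data$groups))
  ex <- exp(eta - gmax[sid])
  denom <- drop(rowsum(ex, sid))
  p <- ex / denom[sid]
  ll <- sum(eta[data$is_case == 1L]) - sum(log(denom) + gmax)
  w <- data$is_case - p
  grad <- drop(crossprod(X, w))
  Pc <- rowsum(X * p, sid)
  hess <- -(crossprod(X * sqrt(p)) - crossprod(Pc))
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Fit a conditional logistic regression by damped Newton-Raphson
#'
#' Maximizes the stratified conditional log-likelihood with analytic
#' gradient and Hessian, halving the step whenever it fails to improve
#' the log-likelihood. Convergence is declared when the largest absolute
#' gradient component falls below `tol`. The coefficient covariance is
#' the inverse observed information at the optimum, and
#' `aic = -2 loglik + 2 k`.
#'
#' @param data A `clr_data` object.
#' @param tol Gradient sup-norm tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return Object of class `clr_fit`: `coefficients`, `vcov`, `loglik`,
#'   `aic`, `n_strata`, `n_parameters`, `converged`, `iterations`,
#'   `diagnostic` (message when flagged).
#' @export
fit_clr <- function(data, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(data, "clr_data"))
  k <- ncol(data$X)
  n_strata <- length(data$groups)
  flag <- function(msg, theta = rep(NA_real_, k), ll = NA_real_, it = 0L) {
    structure(list(coefficients = theta,
                   vcov = matrix(NA_real_, k, k),
                   loglik = ll, aic = if (is.na(ll)) NA_real_
                   else -2 * ll + 2 * k,
                   n_strata = n_strata, n_parameters = k,
                   converged = FALSE, iterations = it, diagnostic = msg),
              class = "clr_fit")
  }
  if (n_strata == 0L) return(flag("no informative strata; theta undefined"))

  theta <- numeric(k)
  cur <- conditional_loglik(theta, data)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (max(abs(cur$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hessian, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {
      return(flag("singular information matrix (collinear design?)",
                  theta, cur$loglik, it))
    }
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      new <- conditional_loglik(cand, data)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 2^-30) {
        return(flag("step-halving failed to improve the likelihood",
                    theta, cur$loglik, it))
      }
    }
    theta <- theta + lambda * step
    cur <- new
    if (max(abs(theta)) > 1e4) {
      return(flag("coefficients diverging (possible separation)",
                  theta, cur$loglik, it))
    }
  }
  if (!converged && max(abs(cur$gradient)) < tol) converged <- TRUE
  vc <- tryCatch(solve(-cur$hessian), error = function(e) {
    matrix(NA_real_, k, k)
  })
  vc <- (vc + t(vc)) / 2
  structure(list(coefficients = named(theta, colnames(data$X)),
                 vcov = vc,
                 loglik = cur$loglik,
                 aic = -2 * cur$loglik + 2 * k,
                 n_strata = n_strata, n_parameters = k,
                 converged = converged, iterations = it,
                 diagnostic = if (converged) NA_character_
                 else "not converged in max_iter"),
            class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf(
    "conditional logistic fit: %d strata, %d parameters\nloglik %.4f, AIC %.4f, %s in %d iteration(s)\n",
    x$n_strata, x$n_parameters, x$loglik, x$aic,
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$iterations))
  if (!is.na(x$diagnostic)) cat("diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Select spline degrees of freedom by AIC over a grid
#'
#' Fits the conditional logistic DLNM for every combination of exposure
#' and lag degrees of freedom (the default grid, df_var in {3, 4} and
#' df_lag in {2, 3, 4, 5}, fits 8 models), with relative-humidity terms
#' (when present) given the same structure as the temperature terms, and
#' returns the AIC-minimizing pair together with the full table.
#' Non-converged fits are recorded but excluded from the arg-min with a
#' warning. Ties within 1e-6 go to the smaller total df (parsimony).
#'
#' @param strata A `cco_strata` object.
#' @param var_df_grid,lag_df_grid Integer grids.
#' @param include_rh Include relative-humidity cross-basis terms
#'   (default `TRUE`).
#' @param reference Reference exposure for the stored specs (default:
#'   minimum pooled lagged temperature).
#' @return List with `var_df`, `lag_df`, `table` (one row per
#'   combination: dfs, loglik, aic, converged), `fit` (the winning
#'   `clr_fit`), `spec_temperature`, `spec_rh` (winning specs).
#' @export
aic_grid_select <- function(strata, var_df_grid = c(3L, 4L),
                            lag_df_grid = 2:5, include_rh = TRUE,
                            reference = NULL) {
  stopifnot(length(var_df_grid) >= 1L, length(lag_df_grid) >= 1L)
  if (is.null(reference)) reference <- min(strata$lag_temperature)
  grid <- expand.grid(var_df = as.integer(var_df_grid),
                      lag_df = as.integer(lag_df_grid))
  fits <- vector("list", nrow(grid))
  specs <- vector("list", nrow(grid))
  tab <- grid
  tab$k <- NA_integer_
  tab$loglik <- NA_real_
  tab$aic <- NA_real_
  tab$converged <- FALSE
  for (i in seq_len(nrow(grid))) {
    st <- fit_dlnm(strata, var_df = grid$var_df[i], lag_df = grid$lag_df[i],
                   include_rh = include_rh, reference = reference)
    fits[[i]] <- st
    tab$k[i] <- st$fit$n_parameters
    tab$loglik[i] <- st$fit$loglik
    tab$aic[i] <- st$fit$aic
    tab$converged[i] <- st$fit$converged
  }
  ok <- which(tab$converged)
  if (!length(ok)) stop("no fit in the AIC grid converged", call. = FALSE)
  if (length(ok) < nrow(tab)) {
    warning(sprintf("%d of %d fits did not converge and were excluded",
                    nrow(tab) - length(ok), nrow(tab)))
  }
  best_aic <- min(tab$aic[ok])
  cand <- ok[tab$aic[ok] <= best_aic + 1e-6]
  cand <- cand[order(tab$var_df[cand] + tab$lag_df[cand])]
  w <- cand[1L]
  c(list(var_df = tab$var_df[w], lag_df = tab$lag_df[w], table = tab),
    fits[[w]])
}

#' Fit the temperature (+ relative humidity) DLNM on built strata
#'
#' Convenience wrapper: builds percentile-knot cross-basis specs from the
#' strata's pooled lagged exposures, expands both design blocks, and runs
#' [fit_clr()]. The relative-humidity block, when included, mirrors the
#' structure of the temperature block.
#'
#' @param strata A `cco_strata` object.
#' @param var_df,lag_df Degrees of freedom for the exposure and lag
#'   dimensions.
#' @param include_rh Include the relative-humidity cross-basis.
#' @param reference Reference temperature for contrasts (default: minimum
#'   pooled lagged temperature).
#' @param lag_type Lag-basis type, `"ns"` (default) or `"identity"` for
#'   an unconstrained lag structure.
#' @return List with `fit` (a `clr_fit`), `spec_temperature`, `spec_rh`
#'   (or `NULL`), `data` (the `clr_data`), and the column index ranges
#'   `idx_temperature`, `idx_rh`.
#' @export
fit_dlnm <- function(strata, var_df = 3L, lag_df = 4L, include_rh = TRUE,
                     reference = NULL, lag_type = "ns") {
  if (is.null(reference)) reference <- min(strata$lag_temperature)
  spec_t <- cross_basis_spec(
    var_spline_spec(strata$lag_temperature, var_df),
    max_lag = strata$max_lag, lag_df = lag_df, lag_type = lag_type,
    reference = reference)
  cb_t <- cross_basis(strata$lag_temperature, spec_t)
  colnames(cb_t) <- paste0("T.", colnames(cb_t))
  spec_r <- NULL
  if (include_rh) {
    spec_r <- cross_basis_spec(
      var_spline_spec(strata$lag_rh, var_df),
      max_lag = strata$max_lag, lag_df = lag_df, lag_type = lag_type,
      reference = stats::median(strata$lag_rh))
    cb_r <- cross_basis(strata$lag_rh, spec_r)
    colnames(cb_r) <- paste0("RH.", colnames(cb_r))
    data <- clr_design(strata, cb_t, cb_r)
  } else {
    data <- clr_design(strata, cb_t)
  }
  fit <- fit_clr(data)
  kt <- ncol(cb_t)
  list(fit = fit,
       spec_temperature = spec_t,
       spec_rh = spec_r,
       data = data,
       idx_temperature = seq_len(kt),
       idx_rh = if (include_rh) kt + seq_len(kt) else integer())
}
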