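# shared fixture builders; everything is generated in code at test time

# tiny grid series: `cells` cells x `days` days starting at `start`
make_grid <- function(cells = 2L, days = 5L, start = "2003-06-01",
                      seed = 11L) {
  set.seed(seed)
  dates <- seq(as.Date(start), by = "day", length.out = days)
  do.call(rbind, lapply(seq_len(cells), function(c) {
    data.frame(cell_id = paste0("c", c), date = dates,
               temperature = round(stats::rnorm(days, 15, 5), 3),
               specific_humidity = round(stats::runif(days, 0.002, 0.012), 6),
               pressure = round(stats::rnorm(days, 1010, 4), 2),
               stringsAsFactors = FALSE)
  }))
}

# random case-crossover strata with known structure, for likelihood tests:
# n_strata strata of random size 2..5 and k covariates
make_random_strata <- function(n_strata = 20L, k = 4L, seed = 42L,
                               min_rows = 2L, max_rows = 5L) {
  set.seed(seed)
  sizes <- sample(min_rows:max_rows, n_strata, replace = TRUE)
  X <- matrix(stats::rnorm(sum(sizes) * k), ncol = k)
  sid <- rep(seq_len(n_strata), sizes)
  is_case <- unlist(lapply(sizes, function(s) {
    v <- integer(s); v[sample.int(s, 1L)] <- 1L; v
  }))
  structure(list(X = X, stratum = sid, is_case = is_case,
                 groups = unname(split(seq_along(sid), sid)),
                 n_noninformative = 0L), class = "clr_data")
}

# plain-loop conditional logistic log-likelihood / gradient / hessian:
# independent enumeration of the per-stratum conditional probabilities
bruteforce_clr <- function(theta, X, sid, is_case) {
  ll <- 0; k <- length(theta)
  grad <- numeric(k); hess <- matrix(0, k, k)
  for (s in unique(sid)) {
    ix <- which(sid == s)
    num <- exp(as.numeric(X[ix, , drop = FALSE] %*% theta))
    p <- num / sum(num)
    case <- ix[is_case[ix] == 1L]
    ll <- ll + log(p[match(case, ix)])
    xbar <- numeric(k); xxbar <- matrix(0, k, k)
    for (r in seq_along(ix)) {
      xr <- X[ix[r], ]
      xbar <- xbar + p[r] * xr
      xxbar <- xxbar + p[r] * tcrossprod(xr)
    }
    grad <- grad + X[case, ] - xbar
    hess <- hess - (xxbar - tcrossprod(xbar))
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

# small exposure table for one or two units with prescribed temperatures
make_exposure <- function(units = "u1", start = "2003-05-01", days = 92L,
                          temperature = NULL, rh = NULL, seed = 5L) {
  set.seed(seed)
  dates <- seq(as.Date(start), by = "day", length.out = days)
  do.call(rbind, lapply(units, function(u) {
    data.frame(
      unit_id = u, date = dates,
      temperature = if (is.null(temperature))
        round(stats::rnorm(days, 18, 6), 2) else temperature,
      relative_humidity = if (is.null(rh))
        round(stats::runif(days, 30, 90), 1) else rh,
      stringsAsFactors = FALSE)
  }))
}

# events on a given unit/date set
make_events <- function(dates, unit = "u1") {
  data.frame(record_id = paste0("r", seq_along(dates)),
             admission_date = as.Date(dates), unit_id = unit,
             stringsAsFactors = FALSE)
}
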