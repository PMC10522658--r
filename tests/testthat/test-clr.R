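test_that("log-likelihood at zero is -sum log n_c; identical rows are inert", {
  d <- make_random_strata(10L, 3L, seed = 1L)
  sizes <- lengths(d$groups)
  ll0 <- conditional_loglik(numeric(3), d)
  expect_equal(ll0$loglik, -sum(log(sizes)), tolerance = 1e-12)

  # a stratum whose rows are all identical contributes -log n_c at any theta
  X <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  d1 <- structure(list(X = X, stratum = rep(1L, 4), is_case = c(1L, 0, 0, 0),
                       groups = list(1:4), n_noninformative = 0L),
                  class = "clr_data")
  for (th in list(c(0, 0, 0), c(1, -2, 0.5), c(10, 10, 10))) {
    expect_equal(conditional_loglik(th, d1)$loglik, -log(4),
                 tolerance = 1e-12)
  }
  expect_error(conditional_loglik(numeric(2), d), "columns")
})

test_that("likelihood, gradient and hessian match brute-force enumeration", {
  d <- make_random_strata(20L, 6L, seed = 7L)
  set.seed(8)
  for (rep in 1:3) {
    theta <- stats::rnorm(6, 0, 0.7)
    got <- conditional_loglik(theta, d)
    want <- bruteforce_clr(theta, d$X, d$stratum, d$is_case)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_equal(unname(got$gradient), want$gradient, tolerance = 1e-10)
    expect_equal(unname(got$hessian), unname(want$hessian),
                 tolerance = 1e-10)
  }
})

test_that("the conditional likelihood is concave", {
  set.seed(15)
  for (rep in 1:5) {
    d <- make_random_strata(8L, 3L, seed = 100L + rep)
    theta <- stats::rnorm(3)
    h <- conditional_loglik(theta, d)$hessian
    expect_lte(max(eigen(h, symmetric = TRUE,
                         only.values = TRUE)$values), 1e-10)
  }
})

test_that("within-stratum constant shifts leave the likelihood invariant", {
  d <- make_random_strata(12L, 4L, seed = 3L)
  set.seed(4)
  shift <- stats::rnorm(length(d$groups), 0, 5)
  d2 <- d
  d2$X[, 2] <- d2$X[, 2] + shift[d$stratum]
  theta <- stats::rnorm(4, 0, 0.5)
  expect_equal(conditional_loglik(theta, d)$loglik,
               conditional_loglik(theta, d2)$loglik, tolerance = 1e-10)
})

test_that("Newton fit recovers a known coefficient and satisfies AIC", {
  # single covariate with strong signal; conditional sampling of the case
  set.seed(99)
  n_strata <- 5000L
  beta <- 0.8
  rows <- 4L
  X <- matrix(stats::rnorm(n_strata * rows), ncol = 1)
  sid <- rep(seq_len(n_strata), each = rows)
  eta <- beta * X[, 1]
  is_case <- integer(n_strata * rows)
  for (s in seq_len(n_strata)) {
    ix <- which(sid == s)
    p <- exp(eta[ix]) / sum(exp(eta[ix]))
    is_case[ix[sample.int(rows, 1L, prob = p)]] <- 1L
  }
  d <- structure(list(X = X, stratum = sid, is_case = is_case,
                      groups = unname(split(seq_along(sid), sid)),
                      n_noninformative = 0L), class = "clr_data")
  fit <- fit_clr(d)
  expect_true(fit$converged)
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$coefficients[1] - beta), 3 * se)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 1, tolerance = 1e-12)
  # gradient at the optimum is numerically zero
  expect_lt(max(abs(conditional_loglik(fit$coefficients, d)$gradient)), 1e-6)
})

test_that("degenerate designs are flagged, not thrown", {
  # all rows identical in every stratum -> non-informative, theta undefined
  X <- matrix(1, 8, 2)
  sid <- rep(1:2, each = 4)
  st <- structure(list(rows = data.frame(
    stratum_id = sid, unit_id = "u", date = as.Date("2000-01-01") + 1:8,
    is_case = rep(c(1L, 0L, 0L, 0L), 2)),
    lag_temperature = X, lag_rh = X, events = data.frame(id = 1:2),
    max_lag = 1L, n_dropped = 0L), class = "cco_strata")
  expect_message(d <- clr_design(st, X), "non-informative")
  fit <- fit_clr(d)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$coefficients)))
  expect_match(fit$diagnostic, "no informative")
})

test_that("fit is invariant to stratum and row ordering", {
  d <- make_random_strata(30L, 3L, seed = 17L)
  fit1 <- fit_clr(d)
  set.seed(18)
  perm <- sample(nrow(d$X))
  d2 <- structure(list(X = d$X[perm, , drop = FALSE],
                       stratum = d$stratum[perm],
                       is_case = d$is_case[perm]), class = "clr_data")
  # rebuild groups as clr_design would (rows of a stratum contiguous)
  ord <- order(d2$stratum)
  d2 <- structure(list(X = d2$X[ord, , drop = FALSE],
                       stratum = d2$stratum[ord],
                       is_case = d2$is_case[ord],
                       groups = unname(split(seq_along(ord),
                                             d2$stratum[ord])),
                       n_noninformative = 0L), class = "clr_data")
  fit2 <- fit_clr(d2)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-9)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("size-2 strata equal no-intercept logistic regression on differences", {
  set.seed(23)
  n <- 400L
  k <- 3L
  beta <- c(0.5, -0.3, 0.2)
  x_case <- matrix(stats::rnorm(n * k), n, k)
  x_ctrl <- matrix(stats::rnorm(n * k), n, k)
  # draw which member is the case from the conditional probability
  p_first <- 1 / (1 + exp(-(x_case - x_ctrl) %*% beta))
  swap <- stats::runif(n) > p_first
  tmp <- x_case[swap, ]; x_case[swap, ] <- x_ctrl[swap, ]
  x_ctrl[swap, ] <- tmp

  X <- matrix(NA_real_, 2 * n, k)
  X[seq(1, 2 * n, 2), ] <- x_case
  X[seq(2, 2 * n, 2), ] <- x_ctrl
  sid <- rep(seq_len(n), each = 2)
  is_case <- rep(c(1L, 0L), n)
  d <- structure(list(X = X, stratum = sid, is_case = is_case,
                      groups = unname(split(seq_along(sid), sid)),
                      n_noninformative = 0L), class = "clr_data")
  fit <- fit_clr(d)

  diffs <- x_case - x_ctrl
  glmfit <- stats::glm(rep(1, n) ~ diffs - 1, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(glmfit)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(glmfit)),
               tolerance = 1e-6)
})

test_that("estimates agree with an established conditional-logistic fitter", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- make_random_strata(60L, 3L, seed = 77L)
  fit <- fit_clr(d)
  y <- d$is_case
  df <- data.frame(y = y, d$X, sid = d$stratum)
  cl <- survival::clogit(y ~ X1 + X2 + X3 + strata(sid), data = df)
  expect_equal(unname(fit$coefficients), unname(stats::coef(cl)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(cl)), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(stats::vcov(cl)), tolerance = 1e-5)
})

test_that("AIC grid fits all eight default combinations and picks the minimum", {
  tr <- calibration_truth(900, surface = list(family = "linear",
                                              per10 = 0.3, reference = 0),
                          seed = 5L)
  grid <- simulate_weather(tr, 5L)
  xw <- data.frame(unit_id = sprintf("unit%03d", 1:6),
                   cell_id = sprintf("cell%02d", c(1:4, 1:2)), weight = 1)
  exposure <- build_exposure_table(grid, xw)
  adm <- simulate_admissions(tr, exposure, seed = 6L)
  excl <- apply_exclusions(adm)
  cl <- classify_admissions(excl$records, example_cause_map())
  svi <- data.frame(unit_id = unique(exposure$unit_id),
                    svi_value = seq(0, 1, length.out = 6), tertile = rep(1:3, 2))
  ev <- extract_case_series(excl$records, "alcohol", cl, svi)
  st <- suppressMessages(build_strata(ev, exposure))

  sel <- aic_grid_select(st)
  expect_equal(nrow(sel$table), 8L)
  expect_setequal(sel$table$var_df, c(3L, 4L))
  expect_setequal(sel$table$lag_df, 2:5)
  # aic = -2 loglik + 2k recomputed externally, exactly
  expect_equal(sel$table$aic, -2 * sel$table$loglik + 2 * sel$table$k,
               tolerance = 1e-12)
  # exhaustive refit-and-compare loop reproduces the selection
  refit_aic <- mapply(function(v, l) {
    fit_dlnm(st, v, l, reference = min(st$lag_temperature))$fit$aic
  }, sel$table$var_df, sel$table$lag_df)
  expect_equal(refit_aic, sel$table$aic, tolerance = 1e-8)
  best <- which.min(sel$table$aic)
  expect_equal(c(sel$var_df, sel$lag_df),
               c(sel$table$var_df[best], sel$table$lag_df[best]))

  # single-element grids return that element
  one <- aic_grid_select(st, 3L, 4L)
  expect_equal(c(one$var_df, one$lag_df), c(3L, 4L))
  expect_equal(nrow(one$table), 1L)
})
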