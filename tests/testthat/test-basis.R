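# truncated-power construction of the natural cubic spline space on the
# knot sequence {b0, interior..., b1}: basis {1, x, d_j(x) - d_{K-1}(x)}
# with d_j(x) = ((x - k_j)^3_+ - (x - k_K)^3_+) / (k_K - k_j).
# Independent of the implementation under test.
natural_tp_basis <- function(x, interior, boundary) {
  kn <- sort(c(boundary, interior))
  K <- length(kn)
  pp <- function(v) pmax(v, 0)^3
  d <- function(j) (pp(x - kn[j]) - pp(x - kn[K])) / (kn[K] - kn[j])
  cols <- list(rep(1, length(x)), x)
  for (j in seq_len(K - 2L)) cols[[j + 2L]] <- d(j) - d(K - 1L)
  do.call(cbind, cols)
}

# residual of regressing each column of A on the column space of B
span_residual <- function(A, B) {
  fit <- qr(B)
  max(abs(A - B %*% qr.coef(fit, A)))
}

test_that("natural spline basis spans the truncated-power natural space", {
  set.seed(3)
  sp <- spline_spec(df = 3L, boundary_knots = c(-5, 25),
                    interior_knots = c(2, 12))
  probe <- sort(c(stats::runif(10, -15, 35), -5, 25, 2, 12))
  ns_mat <- natural_spline_basis(probe, sp)
  tp <- natural_tp_basis(probe, c(2, 12), c(-5, 25))
  # each ns column lies in the truncated-power space (with intercept) ...
  expect_lt(span_residual(ns_mat, tp), 1e-8)
  # ... and vice versa (mutual span, including extrapolation region)
  expect_lt(span_residual(tp, cbind(1, ns_mat)), 1e-8)
})

test_that("df = 1 is affine in x; tails are linear; C2 at interior knots", {
  sp1 <- spline_spec(1L, c(0, 10))
  x <- seq(-5, 15, by = 0.5)
  b <- natural_spline_basis(x, sp1)
  expect_equal(ncol(b), 1L)
  expect_lt(max(abs(diff(b[, 1], differences = 2))), 1e-12)  # affine

  sp <- spline_spec(4L, c(0, 10), c(2.5, 5, 7.5))
  fine <- seq(-6, 16, by = 0.01)
  bb <- natural_spline_basis(fine, sp)
  # second differences vanish beyond the boundary knots (linearity)
  left <- fine < -0.1; right <- fine > 10.1
  for (j in seq_len(ncol(bb))) {
    expect_lt(max(abs(diff(bb[left, j], differences = 2))), 1e-9)
    expect_lt(max(abs(diff(bb[right, j], differences = 2))), 1e-9)
    # C2 continuity: third differences stay bounded through the knots
    # (a jump in value/slope/curvature would blow up h^-3-scaled diffs)
    d2 <- diff(bb[, j], differences = 2) / 0.01^2
    expect_lt(max(abs(diff(d2))) * 0.01, 0.5)
  }
  expect_error(spline_spec(3L, c(0, 10), c(5, 5)), "degenerate")
})

test_that("percentile knot placement follows the df convention", {
  x <- 0:100
  sp <- var_spline_spec(x, 3L)
  expect_equal(sp$interior_knots, c(100 / 3, 200 / 3), tolerance = 1e-9)
  expect_equal(sp$boundary_knots, c(0, 100))
  expect_equal(var_spline_spec(x, 1L)$df, 1L)
})

test_that("lag basis has an intercept, log-scale knots, identity option", {
  lb <- lag_basis(6L, 4L)
  expect_equal(dim(lb), c(7L, 4L))
  expect_true(all(lb[, 1] == 1))
  lb1 <- lag_basis(6L, 1L)
  expect_true(all(lb1 == 1))
  id <- lag_basis(1L, 2L, type = "identity")
  expect_equal(id, diag(2), ignore_attr = TRUE)
  expect_error(lag_basis(6L, 8L), "max_lag")
})

test_that("cross-basis dimensions and separability", {
  set.seed(7)
  x <- matrix(stats::rnorm(5 * 7, 15, 5), 5, 7)
  spec <- cross_basis_spec(var_spline_spec(x, 3L), max_lag = 6L,
                           lag_df = 4L, reference = min(x))
  cb <- cross_basis(x, spec)
  expect_equal(dim(cb), c(5L, 12L))  # df_var 3 x df_lag 4

  # constant exposure across lags: entry (j,k) = v_j(x) * sum_l L_k(l)
  xc <- matrix(17.3, 2, 7)
  cbc <- cross_basis(xc, spec)
  v <- natural_spline_basis(17.3, spec$var_spec)
  lsum <- colSums(spec$lag_matrix)
  expect_equal(unname(cbc[1, ]),
               as.vector(t(outer(drop(v), lsum))), tolerance = 1e-12)

  xbad <- x; xbad[3, 2] <- NA
  expect_error(cross_basis(xbad, spec), "row 3")
})

test_that("cross-basis equals a direct triple-loop summation", {
  set.seed(12)
  x <- matrix(stats::rnorm(5 * 7, 15, 6), 5, 7)
  spec <- cross_basis_spec(var_spline_spec(x, 3L), max_lag = 6L,
                           lag_df = 4L, reference = min(x))
  cb <- cross_basis(x, spec)
  dv <- 3L; dl <- 4L
  for (i in 1:5) {
    for (j in seq_len(dv)) {
      for (k in seq_len(dl)) {
        acc <- 0
        for (l in 0:6) {
          acc <- acc + natural_spline_basis(x[i, l + 1L],
                                            spec$var_spec)[1, j] *
            spec$lag_matrix[l + 1L, k]
        }
        expect_equal(unname(cb[i, (j - 1L) * dl + k]), unname(acc),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("cumulative contrast matches per-lag brute force and its algebra", {
  set.seed(21)
  x <- matrix(stats::rnorm(40 * 7, 15, 6), 40, 7)
  spec <- cross_basis_spec(var_spline_spec(x, 3L), max_lag = 6L,
                           lag_df = 4L, reference = min(x))
  k <- 12L
  theta <- stats::rnorm(k, 0, 0.1)
  A <- matrix(stats::rnorm(k * k), k)
  Sigma <- crossprod(A) / k

  at <- 22
  # brute force: per-lag contrast summed over lags, and the quadratic form
  v_at <- natural_spline_basis(at, spec$var_spec)
  v_ref <- natural_spline_basis(spec$reference, spec$var_spec)
  g <- numeric(k)
  for (j in 1:3) {
    for (kk in 1:4) {
      for (l in 0:6) {
        g[(j - 1L) * 4L + kk] <- g[(j - 1L) * 4L + kk] +
          (v_at[1, j] - v_ref[1, j]) * spec$lag_matrix[l + 1L, kk]
      }
    }
  }
  cc <- cumulative_contrast(theta, Sigma, spec, at)
  expect_equal(cc$estimate, sum(g * theta), tolerance = 1e-12)
  expect_equal(cc$variance, as.numeric(g %*% Sigma %*% g), tolerance = 1e-12)

  # additivity over lag singletons, to 1e-12
  parts <- vapply(0:6, function(l) {
    cumulative_contrast(theta, Sigma, spec, at, lags = l)$estimate
  }, 0)
  expect_equal(cc$estimate, sum(parts), tolerance = 1e-12)

  # contrast of the reference with itself is exactly (0, 0)
  cc0 <- cumulative_contrast(theta, Sigma, spec, spec$reference)
  expect_identical(cc0$estimate, 0)
  expect_identical(cc0$variance, 0)

  # antisymmetry at fixed theta
  spec_b <- spec; spec_b$reference <- at
  cc_ab <- cumulative_contrast(theta, Sigma, spec_b, spec$reference)
  expect_equal(cc_ab$estimate, -cc$estimate, tolerance = 1e-12)

  # variance is non-negative for any PSD Sigma
  expect_gte(cumulative_contrast(theta, diag(0, k), spec, at)$variance, 0)
})

test_that("linear basis with constant lag collapses to the closed form", {
  # df_var = 1 (affine basis), lag basis constant 1:
  # log-RR = beta * (b(at) - b(ref)) * |lags|, with b the affine column
  x <- matrix(stats::runif(10 * 7, 0, 30), 10, 7)
  spec <- cross_basis_spec(var_spline_spec(x, 1L), max_lag = 6L,
                           lag_df = 1L, reference = 5)
  beta <- 0.37
  b_at <- natural_spline_basis(20, spec$var_spec)[1, 1]
  b_ref <- natural_spline_basis(5, spec$var_spec)[1, 1]
  cc <- cumulative_contrast(beta, matrix(0), spec, 20, lags = 0:6)
  expect_equal(cc$estimate, unname(beta * (b_at - b_ref) * 7),
               tolerance = 1e-12)
  cc2 <- cumulative_contrast(beta, matrix(0), spec, 20, lags = 0:1)
  expect_equal(cc2$estimate, unname(beta * (b_at - b_ref) * 2),
               tolerance = 1e-12)
})
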