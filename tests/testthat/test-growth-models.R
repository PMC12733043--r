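test_that("secondary model is zero at and below t_min and rises above it", {
  expect_identical(mu_max_at(0, b = 0.1, t_min = 5, form = "sqrt"), 0)
  expect_identical(mu_max_at(0, b = 0.1, t_min = 5, form = "linear"), 0)
  expect_identical(mu_max_at(5, b = 0.2, t_min = 5, form = "sqrt"), 0)
  expect_equal(mu_max_at(10, b = 0.2, t_min = 0, form = "sqrt"), 4.0)
  expect_equal(mu_max_at(10, b = 0.2, t_min = 0, form = "linear"), 2.0)

  # continuity at t_min and strict monotonicity above it
  eps <- 1e-9
  expect_lt(mu_max_at(5 + eps, b = 0.2, t_min = 5), 1e-15)
  temps <- seq(5.1, 30, by = 0.1)
  mus <- mu_max_at(temps, b = 0.2, t_min = 5)
  expect_true(all(diff(mus) > 0))
})

test_that("secondary model rejects a non-positive slope", {
  expect_error(mu_max_at(10, b = 0, t_min = 5), "> 0")
  expect_error(mu_max_at(10, b = -0.1, t_min = 5), "> 0")
})

test_that("scale coherence: scaling b scales mu linearly or quadratically", {
  for (k in c(2, 5)) {
    expect_equal(mu_max_at(12, b = k * 0.1, t_min = 2, form = "linear"),
                 k * mu_max_at(12, b = 0.1, t_min = 2, form = "linear"))
    expect_equal(mu_max_at(12, b = k * 0.1, t_min = 2, form = "sqrt"),
                 k^2 * mu_max_at(12, b = 0.1, t_min = 2, form = "sqrt"))
  }
})

test_that("lag duration follows the constant-h0 relation", {
  # fully adapted cells: C0 = 1e8 gives a vanishing lag
  p <- growth_params(2, b = 1, t_min = 0, log10_nmax = 8, log10_c0 = 8)
  v <- model_variant(has_lag = TRUE, secondary_form = "linear")
  expect_lt(lag_at(1, p, v), 1e-7) # mu = 1 at T = 1

  # C0 = 1 and mu = ln 2 per day gives exactly one day of lag
  p2 <- growth_params(2, b = 1, t_min = 0, log10_nmax = 8, log10_c0 = 0)
  expect_equal(lag_at(log(2), p2, v), 1.0)

  # lag is monotonically decreasing in C0
  lags <- vapply(c(-2, -1, 0, 1, 2), function(lc) {
    pp <- growth_params(2, b = 1, t_min = 0, log10_nmax = 8, log10_c0 = lc)
    lag_at(1, pp, v)
  }, numeric(1))
  expect_true(all(diff(lags) < 0))

  # undefined where there is no growth
  expect_error(lag_at(0, p2, v), "undefined")
})

test_that("lag coefficient B satisfies B b^2 = ln(1 + 1/C0)", {
  expect_equal(lag_coefficient_b(1, 1), log(2))
  expect_equal(lag_coefficient_b(1, 2), log(2) / 4)
  expect_lt(lag_coefficient_b(1e8, 1), 2e-8)
  expect_error(lag_coefficient_b(0, 1), "> 0")
  expect_error(lag_coefficient_b(1, -1), "> 0")

  # under the sqrt form, 1/sqrt(lambda) is linear in (T - t_min)
  p <- growth_params(2, b = 0.15, t_min = 2, log10_nmax = 9, log10_c0 = -0.5)
  v <- model_variant(has_lag = TRUE, secondary_form = "sqrt")
  temps <- c(6, 10, 14, 18)
  inv_sqrt_lag <- 1 / sqrt(lag_at(temps, p, v))
  B <- lag_coefficient_b(10^p$log10_c0, p$b)
  expect_equal(inv_sqrt_lag, (temps - p$t_min) / sqrt(B))
})

test_that("baranyi curve honours its limits and monotonicity", {
  expect_equal(baranyi_log_count(0, 1.2, 0.7, 2, 8), 2)
  expect_equal(baranyi_log_count(c(0, 3, 10), 0, 1, 2, 8), c(2, 2, 2))

  t <- seq(0, 40, length.out = 200)
  y <- baranyi_log_count(t, 0.8, 2, 2, 8)
  expect_true(all(diff(y) >= -1e-12))
  expect_true(all(y >= 2 - 1e-12 & y <= 8 + 1e-12))
  # stationary phase reached: within 1e-3 of the ceiling at lambda + 20/mu
  expect_lt(8 - baranyi_log_count(2 + 20 / 0.8, 0.8, 2, 2, 8), 1e-3)

  expect_error(baranyi_log_count(1, 1, -1, 2, 8), ">= 0")
  expect_error(baranyi_log_count(1, 1, 0, 8, 2), "exceed")
})

test_that("closed form agrees with the ODE solution of the Baranyi system", {
  # a frozen single point: t = 5, mu = 1, lambda = 1, n0 = 2, nmax = 8
  cv <- curve_for(mu = 1, lambda = 1, log10_n0 = 2, log10_nmax = 8)
  ode <- integrate_baranyi_ode(cv$params, cv$variant, cv$temperature,
                               time_grid = c(1e-9, 5))
  expect_equal(baranyi_log_count(5, 1, 1, 2, 8), ode$log10_count[2],
               tolerance = 1e-4)

  # randomized draws: the two routes agree to 1e-4 everywhere
  withr::with_seed(99, {
    for (i in 1:25) {
      mu <- runif(1, 0.05, 3)
      lambda <- runif(1, 0, 5)
      y0 <- runif(1, 1, 4)
      ymax <- y0 + runif(1, 1, 6)
      cv <- curve_for(mu, lambda, y0, ymax)
      tg <- seq(1e-6, lambda + 25 / mu, length.out = 50)
      ode <- integrate_baranyi_ode(cv$params, cv$variant, cv$temperature, tg)
      cf <- baranyi_log_count(tg, mu, lambda, y0, ymax)
      expect_lt(max(abs(ode$log10_count - cf)), 1e-4)
    }
  })
})

test_that("ODE oracle handles the degenerate no-growth cases", {
  p <- growth_params(2.5, b = 0.1, t_min = 5, log10_nmax = 8)
  v <- model_variant()
  out <- integrate_baranyi_ode(p, v, temperature = 2, time_grid = c(0, 5, 10))
  expect_equal(out$log10_count, rep(2.5, 3))
  expect_equal(out$time, c(0, 5, 10))
  expect_error(integrate_baranyi_ode(p, v, 10, c(5, 3)), "increasing")
})

test_that("no-lag consistency: C0 = 1e8 and lambda = 0 give the same curve", {
  v_lag <- model_variant(has_lag = TRUE)
  v_nolag <- model_variant(has_lag = FALSE)
  p_lag <- growth_params(2, b = 0.1, t_min = 0, log10_nmax = 8, log10_c0 = 8)
  p_nolag <- growth_params(2, b = 0.1, t_min = 0, log10_nmax = 8)
  t <- seq(0, 20, length.out = 100)
  for (temp in c(5, 12, 25)) {
    expect_lt(max(abs(predict_log_count(p_lag, v_lag, temp, t) -
                        predict_log_count(p_nolag, v_nolag, temp, t))), 1e-6)
  }
})

test_that("full-model predictions are flat below t_min and consistent above", {
  p <- growth_params(2.4, b = 0.1, t_min = 6.65, log10_nmax = 5.65)
  v <- model_variant()
  expect_equal(predict_log_count(p, v, temperature = 5, time = c(0, 30)),
               c(2.4, 2.4))
  mu <- mu_max_at(15, p$b, p$t_min)
  expect_equal(predict_log_count(p, v, 15, c(0, 2, 4)),
               baranyi_log_count(c(0, 2, 4), mu, 0, 2.4, 5.65))

  # without a stationary phase the ceiling is effectively unbounded
  p_open <- growth_params(2.6, b = 0.58, t_min = 19.76)
  v_open <- model_variant(has_stationary = FALSE)
  y <- predict_log_count(p_open, v_open, 22, c(0, 2, 4))
  expect_true(all(diff(y) > 1))
})

test_that("parameter container enforces its invariants", {
  expect_error(growth_params(2, b = -1, t_min = 0), "positive")
  expect_error(growth_params(5, b = 0.1, t_min = 0, log10_nmax = 4), "exceed")
  expect_error(growth_params(NA, b = 0.1, t_min = 0), "finite")
  expect_error(model_variant(has_lag = NA), "TRUE or FALSE")
  v <- model_variant(has_lag = TRUE)
  p <- growth_params(2, b = 0.1, t_min = 0, log10_nmax = 8)
  expect_error(predict_log_count(p, v, 10, 1), "log10_c0")
})
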