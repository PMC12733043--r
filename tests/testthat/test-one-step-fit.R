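test_that("initial guesses are data-driven and handle degenerate inputs", {
  rc <- reference_condition("kale", "mesophiles", "control")
  d <- simulate_growth_dataset(rc$params, rc$variant, default_design("kale"),
                               replicates = 1, noise_sd = 0, seed = 1)
  g <- initial_guesses(d, rc$variant)
  expect_equal(g$log10_n0, mean(d$log10_count[d$time == 0]))
  expect_equal(g$log10_nmax, max(d$log10_count) + 0.2)
  expect_equal(g$t_min, min(d$temperature) - 5)
  expect_gt(g$b, 0.01)

  # flat (no-growth) data floors the slope guess
  flat <- tidyr::expand_grid(temperature = c(5, 15), time = c(0, 3, 6))
  flat$log10_count <- 3
  expect_equal(initial_guesses(flat, model_variant())$b, 0.01)

  # design invariants: named errors
  one_time <- data.frame(temperature = c(5, 15), time = 0, log10_count = 3)
  expect_error(initial_guesses(one_time, model_variant()),
               class = "freshfit_design_error")
  one_temp <- data.frame(temperature = 5, time = c(0, 3, 6), log10_count = 3)
  expect_error(initial_guesses(one_temp, model_variant()),
               class = "freshfit_design_error")
})

test_that("one-step fit recovers the generating parameters from noise-free data", {
  sets <- list(
    reference_condition("kale", "mesophiles", "control"),
    reference_condition("tomato", "mesophiles", "control"),
    list(params = lagged_params(),
         variant = model_variant(has_lag = TRUE))
  )
  designs <- list(default_design("kale"), default_design("tomato"),
                  default_design("kale"))
  for (i in seq_along(sets)) {
    d <- simulate_growth_dataset(sets[[i]]$params, sets[[i]]$variant,
                                 designs[[i]], replicates = 1, noise_sd = 0,
                                 seed = 1)
    f <- quiet_fit(d, sets[[i]]$variant)
    truth <- unlist(sets[[i]]$params)[names(f$estimates)]
    expect_true(f$converged)
    expect_lt(max(abs(f$estimates - truth)), 1e-3)
    # noise-free data: standard errors collapse to ~0
    expect_lt(max(f$std_errors, na.rm = TRUE), 1e-3)
  }
})

test_that("fitting is deterministic: same data and start, identical result", {
  rc <- reference_condition("tomato", "mesophiles", "control")
  d <- simulate_growth_dataset(rc$params, rc$variant, default_design("tomato"),
                               seed = 7)
  f1 <- quiet_fit(d, rc$variant)
  f2 <- quiet_fit(d, rc$variant)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$aic, f2$aic)
})

test_that("flat data pushes the slope to its lower bound without crashing", {
  flat <- tidyr::expand_grid(temperature = c(5, 15), time = c(0, 2, 4, 6))
  flat$log10_count <- 3
  f <- quiet_fit(flat, model_variant())
  expect_lt(f$estimates[["b"]], 0.01)
  expect_lt(f$rss, 1e-10)
})

test_that("AIC uses the concentrated Gaussian form", {
  fake <- structure(list(rss = 3.0, n_obs = 30L, n_params = 4L),
                    class = "growth_fit")
  expect_equal(compute_aic(fake), 30 * log(0.1) + 10)
  # with identical RSS, dropping one parameter wins by exactly 2
  fake5 <- structure(list(rss = 3.0, n_obs = 30L, n_params = 5L),
                     class = "growth_fit")
  expect_equal(compute_aic(fake5) - compute_aic(fake), 2)
  perfect <- structure(list(rss = 0, n_obs = 30L, n_params = 4L),
                       class = "growth_fit")
  expect_warning(expect_identical(compute_aic(perfect), -Inf), "zero")
})

test_that("residual variance estimate tracks the simulation noise", {
  rc <- reference_condition("kale", "mesophiles", "control")
  d <- simulate_growth_dataset(rc$params, rc$variant, default_design("kale"),
                               replicates = 3, noise_sd = 0.3, seed = 1)
  f <- quiet_fit(d, rc$variant)
  sigma2_hat <- f$rss / (f$n_obs - f$n_params)
  expect_gt(sigma2_hat, 0.09 / 2)
  expect_lt(sigma2_hat, 0.09 * 2)
})

test_that("standard errors scale with the noise level", {
  rc <- reference_condition("kale", "mesophiles", "control")
  med_se <- function(noise_sd) {
    ses <- vapply(replicate_seeds(6, base = 11), function(s) {
      d <- simulate_growth_dataset(rc$params, rc$variant,
                                   default_design("kale"),
                                   noise_sd = noise_sd, seed = s)
      quiet_fit(d, rc$variant)$std_errors
    }, numeric(4))
    apply(ses, 1, median)
  }
  ratio <- med_se(0.3) / med_se(0.15)
  expect_true(all(ratio > 2 * 0.7 & ratio < 2 * 1.3))
})

test_that("growth at a single temperature leaves the secondary model non-identifiable", {
  # growth only above 12 degC: the 22 degC curve alone cannot separate b
  # from t_min (only b * (22 - t_min) is observable)
  p <- growth_params(2.5, b = 0.2, t_min = 12, log10_nmax = 7)
  d <- simulate_growth_dataset(p, model_variant(),
                               design = list(product = "synthetic",
                                             temperatures = c(5, 22),
                                             sampling_days = list(`5` = 0:5,
                                                                  `22` = 0:5)),
                               replicates = 2, noise_sd = 0.1, seed = 3)
  f <- quiet_fit(d, model_variant())
  expect_warning(
    se <- estimate_standard_errors(f, data = d[d$temperature == 22, ]),
    "non-identifiable"
  )
  expect_true(is.na(se[["t_min"]]))
  expect_true(is.na(se[["b"]]))
  expect_false(is.na(se[["log10_nmax"]]))
})

test_that("the complete (lag) model never fits worse than the reduced one", {
  rc <- reference_condition("tomato", "mesophiles", "control")
  for (s in replicate_seeds(5, base = 21)) {
    d <- simulate_growth_dataset(rc$params, rc$variant,
                                 default_design("tomato"), seed = s)
    f <- quiet_select(d)
    cmp <- f$comparison
    expect_lte(cmp$rss[cmp$variant == "lag"],
               cmp$rss[cmp$variant == "no_lag"] + 1e-8)
  }
})

test_that("AIC selection finds a real lag and rejects an absent one", {
  # lag costing ~2.4 log10 units of growth: clearly identifiable
  p_lag <- lagged_params()
  hits <- vapply(replicate_seeds(10, base = 5), function(s) {
    d <- simulate_growth_dataset(p_lag, model_variant(has_lag = TRUE),
                                 default_design("kale"), seed = s)
    f <- quiet_select(d)
    if (f$variant$has_lag) f$estimates[["log10_c0"]] else NA_real_
  }, numeric(1))
  expect_gte(sum(!is.na(hits)), 8)
  expect_lt(abs(median(hits, na.rm = TRUE) - p_lag$log10_c0), 0.3)

  # no lag in truth: parsimony keeps the reduced model
  rc <- reference_condition("kale", "mesophiles", "control")
  nolag <- vapply(replicate_seeds(10, base = 6), function(s) {
    d <- simulate_growth_dataset(rc$params, rc$variant,
                                 default_design("kale"), seed = s)
    !quiet_select(d)$variant$has_lag
  }, logical(1))
  expect_gte(sum(nolag), 8)

  # noise-free no-lag data: the reduced model wins on the parameter penalty
  d0 <- simulate_growth_dataset(rc$params, rc$variant, default_design("kale"),
                                replicates = 1, noise_sd = 0, seed = 1)
  f0 <- quiet_select(d0)
  expect_false(f0$variant$has_lag)
})

test_that("parameter comparison behaves like a two-sample z-test", {
  a <- data.frame(term = c("b", "t_min"), estimate = c(0.10, -5),
                  std.error = c(0.01, 0.9))
  expect_no_error(cmp0 <- compare_parameters(a, a))
  expect_true(all(cmp0$p.value == 1))
  expect_false(any(cmp0$significant))

  # a difference of exactly 1.96 pooled SEs sits at the alpha = 0.05 boundary
  b <- a
  b$estimate[1] <- a$estimate[1] + 1.96 * sqrt(2) * 0.01
  cmp <- compare_parameters(a, b)
  expect_equal(cmp$p.value[1], 0.05, tolerance = 1e-3)

  # parameters present in only one table are dropped with a message
  c_tbl <- rbind(a, data.frame(term = "log10_c0", estimate = 1,
                               std.error = 0.4))
  expect_message(cmp2 <- compare_parameters(a, c_tbl), "omitted")
  expect_setequal(cmp2$term, c("b", "t_min"))
})

test_that("tidy, glance, augment and predict expose the fit consistently", {
  rc <- reference_condition("kale", "mesophiles", "control")
  d <- simulate_growth_dataset(rc$params, rc$variant, default_design("kale"),
                               seed = 2)
  f <- quiet_fit(d, rc$variant)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_setequal(td$term, c("log10_n0", "b", "t_min", "log10_nmax"))
  gl <- glance(f)
  expect_equal(gl$nobs, f$n_obs)
  expect_equal(gl$AIC, f$aic)
  au <- augment(f)
  expect_equal(au$.resid, au$log10_count - au$.fitted)
  expect_equal(sum(au$.resid^2), f$rss, tolerance = 1e-10)
  expect_equal(predict(f, d), au$.fitted)
})
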