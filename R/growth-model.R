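#' Parameter set for the Baranyi-Ratkowsky growth model
#'
#' Bundles the five parameters that describe microbial growth on a product
#' across storage temperatures: the initial and maximum log10 concentrations,
#' the Ratkowsky slope `b`, the theoretical minimum growth temperature
#' `t_min`, and the log10 of the dimensionless physiological-state parameter
#' `C0` that controls the lag phase (large `C0` means cells are fully adapted
#' and there is no lag).
#'
#' @param log10_n0 Initial concentration, log10 CFU/g.
#' @param b Slope of the Ratkowsky secondary model. Under the square-root
#'   form (`secondary_form = "sqrt"`) its units are sqrt(log10 CFU/g/day)/degC;
#'   under the linear form, log10 CFU/g/day/degC.
#' @param t_min Theoretical minimum growth temperature, degC.
#' @param log10_nmax Maximum concentration in the stationary phase,
#'   log10 CFU/g. May be `NA` for experiments that never reach a stationary
#'   phase (used with `has_stationary = FALSE` variants).
#' @param log10_c0 log10 of the physiological-state parameter `C0`. May be
#'   `NA` for no-lag variants (equivalent to `C0 = 1e8`).
#'
#' @return An object of class `growth_params` (a validated named list).
#' @seealso [model_variant()], [predict_log_count()]
#' @examples
#' growth_params(log10_n0 = 2.4, b = 0.1, t_min = -5, log10_nmax = 7.8)
#' @export
growth_params <- function(log10_n0, b, t_min, log10_nmax = NA_real_,
                          log10_c0 = NA_real_) {
  out <- list(
    log10_n0 = as.numeric(log10_n0),
    log10_nmax = as.numeric(log10_nmax),
    b = as.numeric(b),
    t_min = as.numeric(t_min),
    log10_c0 = as.numeric(log10_c0)
  )
  for (nm in c("log10_n0", "b", "t_min")) {
    if (length(out[[nm]]) != 1L || !is.finite(out[[nm]])) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  for (nm in c("log10_nmax", "log10_c0")) {
    if (length(out[[nm]]) != 1L || (!is.na(out[[nm]]) && !is.finite(out[[nm]]))) {
      abort(sprintf("`%s` must be a single finite number or NA.", nm))
    }
  }
  if (out$b <= 0) abort("`b` must be strictly positive.")
  if (!is.na(out$log10_nmax) && out$log10_nmax <= out$log10_n0) {
    abort("`log10_nmax` must exceed `log10_n0`.")
  }
  structure(out, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  log10_n0   = %.4g log10 CFU/g\n", x$log10_n0))
  cat(sprintf("  log10_nmax = %s\n",
              if (is.na(x$log10_nmax)) "NA (no stationary phase)"
              else sprintf("%.4g log10 CFU/g", x$log10_nmax)))
  cat(sprintf("  b          = %.4g\n", x$b))
  cat(sprintf("  t_min      = %.4g degC\n", x$t_min))
  cat(sprintf("  log10_c0   = %s\n",
              if (is.na(x$log10_c0)) "NA (no lag)" else sprintf("%.4g", x$log10_c0)))
  invisible(x)
}

#' Model variant flags for the Baranyi-Ratkowsky model
#'
#' @param has_lag Does the model include a lag phase (fitted `log10_c0`)?
#'   The no-lag variant corresponds to fixing `C0 = 1e8`.
#' @param has_stationary Does the model include a stationary phase (fitted
#'   `log10_nmax`)? When `FALSE` the ceiling is fixed at 15 log10 CFU/g,
#'   effectively unbounded within any realistic observation window.
#' @param secondary_form Form of the Ratkowsky secondary model: `"sqrt"`
#'   (default; `sqrt(mu_max) = b (T - Tmin)`) or `"linear"`
#'   (`mu_max = b (T - Tmin)`).
#'
#' @return An object of class `model_variant`.
#' @examples
#' model_variant(has_lag = TRUE)
#' @export
model_variant <- function(has_lag = FALSE, has_stationary = TRUE,
                          secondary_form = c("sqrt", "linear")) {
  secondary_form <- match.arg(secondary_form)
  if (!is.logical(has_lag) || length(has_lag) != 1L || is.na(has_lag)) {
    abort("`has_lag` must be TRUE or FALSE.")
  }
  if (!is.logical(has_stationary) || length(has_stationary) != 1L ||
      is.na(has_stationary)) {
    abort("`has_stationary` must be TRUE or FALSE.")
  }
  structure(
    list(has_lag = has_lag, has_stationary = has_stationary,
         secondary_form = secondary_form),
    class = "model_variant"
  )
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant> lag: %s | stationary: %s | secondary: %s\n",
              x$has_lag, x$has_stationary, x$secondary_form))
  invisible(x)
}

# ceiling used when the experiment never reaches a stationary phase
.NMAX_UNBOUNDED <- 15

# C0 treated as "fully adapted, no lag"
.C0_NO_LAG <- 1e8

#' Ratkowsky secondary model for the maximum specific growth rate
#'
#' Evaluates the sub-optimal Ratkowsky model. Below (or at) the minimum
#' growth temperature the rate is exactly zero. Above it, the linear form
#' returns `b * (T - t_min)` and the square-root form
#' `(b * (T - t_min))^2`; both are continuous at `T = t_min`.
#'
#' @param temperature Storage temperature(s), degC. Vectorised.
#' @param b Slope of the secondary model (> 0).
#' @param t_min Theoretical minimum growth temperature, degC.
#' @param form `"sqrt"` (default) or `"linear"`.
#'
#' @return Maximum specific growth rate(s), log10 CFU/g/day.
#' @examples
#' mu_max_at(10, b = 0.2, t_min = 0, form = "sqrt") # (0.2 * 10)^2 = 4
#' mu_max_at(0, b = 0.1, t_min = 5)                 # 0: below t_min
#' @export
mu_max_at <- function(temperature, b, t_min, form = c("sqrt", "linear")) {
  form <- match.arg(form)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    abort("`b` must be a single finite number > 0.")
  }
  if (!is.numeric(temperature) || any(!is.finite(temperature))) {
    abort("`temperature` must be finite.")
  }
  excess <- pmax(temperature - t_min, 0)
  if (form == "linear") b * excess else (b * excess)^2
}

#' Lag-phase duration implied by the physiological state parameter
#'
#' The lag phase is tied to the growth rate through the "work to be done"
#' relation `lambda(T) = ln(1 + 1/C0) / mu_max(T)`: the product
#' `mu_max * lambda` is the same at every temperature, which is the unique
#' lag secondary model compatible with the Baranyi primary model. Very large
#' `C0` (1e8) corresponds to fully adapted cells and a vanishing lag.
#'
#' @inheritParams mu_max_at
#' @param params A [growth_params()] object (uses `b`, `t_min`, `log10_c0`).
#' @param variant A [model_variant()] object; its `secondary_form` is used
#'   and `has_lag = FALSE` forces `lambda = 0`.
#'
#' @return Lag duration(s) in days.
#' @examples
#' p <- growth_params(2, b = 0.1, t_min = 0, log10_nmax = 8, log10_c0 = 0)
#' lag_at(10, p, model_variant(has_lag = TRUE))
#' @export
lag_at <- function(temperature, params, variant = model_variant(has_lag = TRUE)) {
  stopifnot(inherits(params, "growth_params"), inherits(variant, "model_variant"))
  if (!variant$has_lag) {
    return(rep(0, length(temperature)))
  }
  c0 <- if (is.na(params$log10_c0)) .C0_NO_LAG else 10^params$log10_c0
  if (c0 <= 0) abort("`C0` must be strictly positive.")
  mu <- mu_max_at(temperature, params$b, params$t_min, variant$secondary_form)
  if (any(mu <= 0)) {
    abort("Lag duration is undefined where `mu_max` is zero (no growth at that temperature).")
  }
  log1p(1 / c0) / mu
}

#' Lag coefficient B of the inverse square-root lag secondary model
#'
#' Under the square-root secondary form, `1 / sqrt(lambda)` is linear in
#' `(T - t_min)` with coefficient `1 / sqrt(B)`, where
#' `B = ln(1 + 1/C0) / b^2`.
#'
#' @param c0 Physiological-state parameter, dimensionless (> 0).
#' @param b Secondary-model slope (> 0).
#'
#' @return The coefficient `B` (> 0).
#' @examples
#' lag_coefficient_b(c0 = 1, b = 1) # ln(2)
#' @export
lag_coefficient_b <- function(c0, b) {
  if (!is.numeric(c0) || any(c0 <= 0) || any(!is.finite(c0))) {
    abort("`c0` must be finite and > 0.")
  }
  if (!is.numeric(b) || any(b <= 0) || any(!is.finite(b))) {
    abort("`b` must be finite and > 0.")
  }
  log1p(1 / c0) / b^2
}

#' Baranyi primary growth curve on the log10 scale
#'
#' Closed-form Baranyi sigmoid evaluated natively in log10 CFU/g with the
#' growth rate expressed in log10 units per day (the curve is invariant
#' under the base change, with the rate rescaled). The lag enters through
#' the standard adjustment function `A(t)`.
#'
#' @param t Time(s), days (>= 0). Vectorised.
#' @param mu_max Maximum specific growth rate, log10 CFU/g/day (>= 0).
#' @param lambda Lag-phase duration, days (>= 0).
#' @param log10_n0 Initial concentration, log10 CFU/g.
#' @param log10_nmax Stationary-phase concentration, log10 CFU/g
#'   (> `log10_n0`).
#'
#' @return log10 concentration(s) at `t`.
#' @examples
#' baranyi_log_count(0:10, mu_max = 1, lambda = 2, log10_n0 = 2, log10_nmax = 8)
#' @export
baranyi_log_count <- function(t, mu_max, lambda, log10_n0, log10_nmax) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (length(mu_max) != 1L || mu_max < 0) abort("`mu_max` must be a single number >= 0.")
  if (length(lambda) != 1L || lambda < 0) abort("`lambda` must be a single number >= 0.")
  if (log10_nmax <= log10_n0) abort("`log10_nmax` must exceed `log10_n0`.")
  if (mu_max == 0) {
    return(rep(log10_n0, length(t)))
  }

  m <- mu_max * log(10) # natural-log rate
  # adjustment function A(t); for lambda = 0 it is exactly t
  if (lambda == 0) {
    a_t <- t
  } else {
    el <- exp(-m * lambda)
    a_t <- t + log(exp(-m * t) * (1 - el) + el) / m
  }

  u <- m * a_t
  d <- (log10_nmax - log10_n0) * log(10)
  # ln(1 + (e^u - 1) e^-d), computed in log space to avoid overflow
  w <- u - d + log1p(-exp(-u))
  corr <- ifelse(u < 1e-12, 0, ifelse(w > 30, w, log1p(exp(w))))
  log10_n0 + mu_max * a_t - corr / log(10)
}

#' Predicted log10 concentration under the full Baranyi-Ratkowsky model
#'
#' Composes the secondary models (growth rate and lag versus temperature)
#' with the Baranyi primary curve. At or below `t_min` the prediction is the
#' flat initial concentration.
#'
#' @param params A [growth_params()] object.
#' @param variant A [model_variant()] object.
#' @param temperature Temperature(s), degC.
#' @param time Time(s), days. `temperature` and `time` are recycled to a
#'   common length.
#'
#' @return A numeric vector of log10 CFU/g predictions.
#' @examples
#' p <- growth_params(2.4, b = 0.1, t_min = -5, log10_nmax = 7.8)
#' predict_log_count(p, model_variant(), temperature = 8, time = 0:10)
#' @export
predict_log_count <- function(params, variant, temperature, time) {
  stopifnot(inherits(params, "growth_params"), inherits(variant, "model_variant"))
  if (variant$has_stationary && is.na(params$log10_nmax)) {
    abort("Variant has a stationary phase but `log10_nmax` is NA.")
  }
  if (variant$has_lag && is.na(params$log10_c0)) {
    abort("Variant has a lag phase but `log10_c0` is NA.")
  }
  n <- max(length(temperature), length(time))
  temperature <- rep_len(temperature, n)
  time <- rep_len(time, n)

  ymax <- if (variant$has_stationary) params$log10_nmax else .NMAX_UNBOUNDED
  out <- rep(params$log10_n0, n)
  for (tt in unique(temperature)) {
    idx <- which(temperature == tt)
    mu <- mu_max_at(tt, params$b, params$t_min, variant$secondary_form)
    if (mu <= 0) next # below t_min: flat at log10_n0
    lam <- if (variant$has_lag) lag_at(tt, params, variant) else 0
    out[idx] <- baranyi_log_count(time[idx], mu, lam, params$log10_n0, ymax)
  }
  out
}

#' Numerical solution of the Baranyi differential system
#'
#' Integrates the Baranyi ODE system (log10 concentration plus the
#' physiological-state variable Q) with `deSolve::lsoda`. This is an
#' independent route to the same curve as [predict_log_count()] and exists
#' to cross-validate the closed form; it is not used by the fitting code.
#'
#' @inheritParams predict_log_count
#' @param time_grid Increasing vector of times (days) at which to report the
#'   solution; must start at 0 or later.
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#'
#' @return A tibble with columns `time` and `log10_count`.
#' @examples
#' p <- growth_params(2, b = 0.1, t_min = 0, log10_nmax = 8)
#' integrate_baranyi_ode(p, model_variant(), 15, seq(0, 10, by = 1))
#' @export
integrate_baranyi_ode <- function(params, variant, temperature, time_grid,
                                  rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "growth_params"), inherits(variant, "model_variant"))
  if (is.unsorted(time_grid, strictly = TRUE)) {
    abort("`time_grid` must be strictly increasing.")
  }
  if (any(time_grid < 0)) abort("`time_grid` must be non-negative.")
  if (length(temperature) != 1L) abort("`temperature` must be a single value.")

  mu <- mu_max_at(temperature, params$b, params$t_min, variant$secondary_form)
  ymax <- if (variant$has_stationary) params$log10_nmax else .NMAX_UNBOUNDED
  if (mu <= 0) {
    return(tibble::tibble(time = time_grid,
                          log10_count = rep(params$log10_n0, length(time_grid))))
  }
  lam <- if (variant$has_lag) lag_at(temperature, params, variant) else 0
  m <- mu * log(10)
  # Q(0) chosen so that ln(1 + 1/Q0) = m * lambda, i.e. the closed form's lag
  lnq0 <- if (lam == 0) 50 else -log(expm1(m * lam))

  rhs <- function(t, state, parms) {
    alpha <- stats::plogis(state[["lnq"]])
    dy <- mu * alpha * (1 - 10^(state[["y"]] - ymax))
    list(c(y = dy, lnq = m))
  }
  grid <- if (time_grid[1] > 0) c(0, time_grid) else time_grid
  sol <- deSolve::lsoda(c(y = params$log10_n0, lnq = lnq0), grid, rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE solver failed (istate = %d).", attr(sol, "istate")[1]))
  }
  sol <- as.data.frame(sol)
  keep <- match(time_grid, sol$time)
  tibble::tibble(time = time_grid, log10_count = sol$y[keep])
}
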