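# One-step (global) fitting of the Baranyi-Ratkowsky model: all growth curves
# of one product x microorganism x packaging condition, across temperatures,
# enter a single least-squares objective on the log10 scale.

.free_param_names <- function(variant) {
  nms <- c("log10_n0", "b", "t_min")
  if (variant$has_stationary) nms <- c(nms, "log10_nmax")
  if (variant$has_lag) nms <- c(nms, "log10_c0")
  nms
}

.param_bounds <- function(variant, data) {
  upper_tmin <- max(data$temperature) - 0.1
  lower <- c(log10_n0 = 0, b = 1e-6, t_min = -30,
             log10_nmax = 0, log10_c0 = -5)
  upper <- c(log10_n0 = 15, b = 5, t_min = upper_tmin,
             log10_nmax = 15, log10_c0 = 8)
  nms <- .free_param_names(variant)
  list(lower = lower[nms], upper = upper[nms])
}

.as_growth_params <- function(est, variant) {
  growth_params(
    log10_n0 = est[["log10_n0"]],
    b = est[["b"]],
    t_min = est[["t_min"]],
    log10_nmax = if (variant$has_stationary) est[["log10_nmax"]] else NA_real_,
    log10_c0 = if (variant$has_lag) est[["log10_c0"]] else NA_real_
  )
}

# residual vector for nls.lm; guards the (transient) nmax <= n0 corner of the
# box so the objective stays defined everywhere within the bounds
.residual_fun <- function(par, variant, data) {
  est <- par
  if (variant$has_stationary) {
    est[["log10_nmax"]] <- max(est[["log10_nmax"]], est[["log10_n0"]] + 1e-3)
  }
  p <- .as_growth_params(est, variant)
  data$log10_count - predict_log_count(p, variant, data$temperature, data$time)
}

.check_design <- function(data) {
  if (!all(c("temperature", "time", "log10_count") %in% names(data))) {
    abort("`data` needs columns `temperature`, `time`, `log10_count`.",
          class = "freshfit_design_error")
  }
  if (any(data$time < 0)) {
    abort("Observation times must be non-negative.",
          class = "freshfit_design_error")
  }
  temps <- unique(data$temperature)
  if (length(temps) < 2L) {
    abort("Design invariant violated: need >= 2 distinct temperatures for the secondary model.",
          class = "freshfit_design_error")
  }
  per_temp <- vapply(split(data$time, data$temperature),
                     function(x) length(unique(x)), integer(1))
  if (any(per_temp < 3L)) {
    bad <- names(per_temp)[per_temp < 3L]
    abort(sprintf(
      "Design invariant violated: need >= 3 distinct time points per temperature (violated at %s degC).",
      paste(bad, collapse = ", ")),
      class = "freshfit_design_error")
  }
  invisible(data)
}

#' Data-driven starting values for the one-step fit
#'
#' Deterministic starting point: `log10_n0` is the mean of the earliest
#' observations, `log10_nmax` the observed maximum plus 0.2, `t_min` the
#' lowest tested temperature minus 5 degC, `b` the slope of a least-squares
#' line through per-temperature crude growth-rate estimates (transformed
#' according to the secondary form), and `log10_c0 = -1` for lag variants.
#' The `b` guess is floored at 0.01 for flat (no-growth) data.
#'
#' @param data A growth dataset: data frame with columns `temperature`
#'   (degC), `time` (days), `log10_count` (log10 CFU/g) and optionally
#'   `censored` (logical).
#' @param variant A [model_variant()].
#'
#' @return A [growth_params()] object usable as `start` in [fit_one_step()].
#' @export
initial_guesses <- function(data, variant = model_variant()) {
  .check_design(data)
  t0 <- min(data$time)
  y0 <- mean(data$log10_count[data$time == t0])
  ymax <- max(data$log10_count) + 0.2

  # crude per-temperature rate: steepest consecutive rise of the mean curve
  rates <- dplyr::group_by(data, .data$temperature) |>
    dplyr::summarise(rate = {
      means <- tapply(.data$log10_count, .data$time, mean)
      tt <- as.numeric(names(means))
      if (length(tt) < 2L) 0 else max(c(0, diff(means) / diff(tt)))
    }, .groups = "drop")

  b0 <- 0.01
  if (any(rates$rate > 0)) {
    y <- if (variant$secondary_form == "sqrt") sqrt(rates$rate) else rates$rate
    sl <- coef(lm(y ~ rates$temperature))[2]
    if (is.finite(sl) && sl > 0.01) b0 <- unname(sl)
  }

  growth_params(
    log10_n0 = max(y0, 0),
    b = b0,
    t_min = min(data$temperature) - 5,
    log10_nmax = if (variant$has_stationary) max(ymax, y0 + 0.5) else NA_real_,
    log10_c0 = if (variant$has_lag) -1 else NA_real_
  )
}

#' One-step global fit of the Baranyi-Ratkowsky model
#'
#' Minimises the sum of squared residuals on the log10 scale jointly over
#' all temperatures of a dataset with bounded Levenberg-Marquardt least
#' squares ([minpack.lm::nls.lm()]). Concentration-like parameters
#' (`log10_n0`, `log10_nmax`, `log10_c0`) are fitted on the log10 scale for
#' identifiability. Observations flagged as censored (below the detection
#' limit) are excluded from the residuals by default, or substituted by the
#' detection limit with `censoring = "substitute"`.
#'
#' @inheritParams initial_guesses
#' @param start Optional [growth_params()] starting point; defaults to
#'   [initial_guesses()].
#' @param censoring How to treat censored observations: `"drop"` (default)
#'   or `"substitute"` (replace by the detection limit).
#' @param detection_limit Detection limit, log10 CFU/g. Defaults to the
#'   dataset's `detection_limit` attribute, or 2.
#' @param n_starts Number of optimiser starts. The first is the
#'   deterministic `start`; additional starts are drawn uniformly within the
#'   parameter box under `seed`, and the best converged solution is kept.
#' @param seed Integer seed for the extra multistart draws (ignored when
#'   `n_starts = 1`).
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#'
#' @return An object of class `growth_fit`: a list with the estimated
#'   `params`, `estimates`, `std_errors`, `rss`, `n_obs`, `n_params`, `aic`,
#'   `variant`, `converged`, `n_iterations`, the data used, and bookkeeping
#'   on censored observations. Methods: [tidy()], [glance()], [augment()],
#'   `predict()`, `print()`, [autoplot()].
#' @examples
#' p <- growth_params(2.4, b = 0.1, t_min = -5, log10_nmax = 7.8)
#' d <- simulate_growth_dataset(p, design = default_design("kale"),
#'                              noise_sd = 0.2, seed = 42)
#' fit <- fit_one_step(d)
#' glance(fit)
#' @export
fit_one_step <- function(data, variant = model_variant(), start = NULL,
                         censoring = c("drop", "substitute"),
                         detection_limit = NULL, n_starts = 1, seed = 1L,
                         maxiter = 200) {
  censoring <- match.arg(censoring)
  .check_design(data)
  detection_limit <- detection_limit %||% attr(data, "detection_limit") %||% 2

  if (!"censored" %in% names(data)) data$censored <- FALSE
  n_censored <- sum(data$censored)
  fit_data <- data
  if (censoring == "drop") {
    fit_data <- data[!data$censored, , drop = FALSE]
  } else {
    fit_data$log10_count[fit_data$censored] <- detection_limit
  }
  .check_design(fit_data)

  start <- start %||% initial_guesses(fit_data, variant)
  stopifnot(inherits(start, "growth_params"))
  bounds <- .param_bounds(variant, fit_data)
  nms <- names(bounds$lower)
  par0 <- vapply(nms, function(nm) start[[nm]], numeric(1))
  par0 <- pmin(pmax(par0, bounds$lower + 1e-9), bounds$upper - 1e-9)

  starts <- list(par0)
  if (n_starts > 1) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        setNames(runif(length(nms), bounds$lower, bounds$upper), nms)
      })
    })
    starts <- c(starts, extra)
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = bounds$lower, upper = bounds$upper,
        fn = .residual_fun, variant = variant, data = fit_data,
        control = minpack.lm::nls.lm.control(maxiter = maxiter)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    abort("Levenberg-Marquardt optimisation failed from every start.")
  }

  est <- best$par
  if (variant$has_stationary) {
    est[["log10_nmax"]] <- max(est[["log10_nmax"]], est[["log10_n0"]] + 1e-3)
  }
  k <- length(est)
  n <- nrow(fit_data)
  rss <- best$deviance
  converged <- best$info %in% 1:4

  fit <- structure(
    list(
      params = .as_growth_params(est, variant),
      estimates = est,
      std_errors = setNames(rep(NA_real_, k), names(est)),
      rss = rss,
      n_obs = n,
      n_params = k,
      aic = NA_real_,
      variant = variant,
      converged = converged,
      n_iterations = best$niter,
      message = best$message,
      data = fit_data,
      n_censored = n_censored,
      censoring = censoring,
      detection_limit = detection_limit,
      start = par0
    ),
    class = "growth_fit"
  )
  fit$aic <- compute_aic(fit)
  fit$std_errors <- estimate_standard_errors(fit)
  fit
}

#' Akaike Information Criterion of a one-step fit
#'
#' Uses the concentrated Gaussian log-likelihood form
#' `AIC = n log(RSS / n) + 2 (k + 1)`, where `k` counts the fitted model
#' parameters and the extra 1 accounts for the residual variance. Only AIC
#' differences are meaningful, so the additive constant is dropped. A
#' perfect fit (`RSS = 0`) returns `-Inf` with a warning.
#'
#' @param fit A `growth_fit` object.
#' @return The AIC (scalar).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$rss == 0) {
    warn("RSS is exactly zero; AIC is -Inf.")
    return(-Inf)
  }
  fit$n_obs * log(fit$rss / fit$n_obs) + 2 * (fit$n_params + 1)
}

#' Standard errors of the one-step parameter estimates
#'
#' Gauss-Newton standard errors `sqrt(diag(sigma2 (J'J)^-1))` with
#' `sigma2 = RSS / (n - k)` and `J` the numeric (central-difference)
#' Jacobian of the model predictions at the optimum. Parameters that lie in
#' a numerically rank-deficient direction of `J` are reported as `NA`
#' (non-identifiable), as happens e.g. when growth occurred at a single
#' temperature only.
#'
#' @param fit A `growth_fit` object.
#' @param data Data to evaluate the Jacobian on; defaults to the data used
#'   in the fit.
#' @return Named vector of standard errors (NA where non-identifiable).
#' @export
estimate_standard_errors <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  data <- data %||% fit$data
  est <- fit$estimates
  k <- length(est)
  n <- nrow(data)
  if (n <= k) {
    warn("Fewer observations than parameters; standard errors unavailable.")
    return(setNames(rep(NA_real_, k), names(est)))
  }

  predict_at <- function(par) {
    # difference steps may poke just outside the feasible box; clamp back
    par[["b"]] <- max(par[["b"]], 1e-12)
    if (fit$variant$has_stationary) {
      par[["log10_nmax"]] <- max(par[["log10_nmax"]], par[["log10_n0"]] + 1e-3)
    }
    p <- .as_growth_params(par, fit$variant)
    predict_log_count(p, fit$variant, data$temperature, data$time)
  }
  jac <- matrix(0, n, k, dimnames = list(NULL, names(est)))
  for (j in seq_len(k)) {
    h <- max(1e-6, 1e-6 * abs(est[[j]]))
    up <- est; up[[j]] <- up[[j]] + h
    dn <- est; dn[[j]] <- dn[[j]] - h
    jac[, j] <- (predict_at(up) - predict_at(dn)) / (2 * h)
  }

  sigma2 <- fit$rss / (n - k)
  sv <- svd(jac)
  tol <- max(sv$d) * 1e-8
  ok <- sv$d > tol
  se <- setNames(rep(NA_real_, k), names(est))
  if (!all(ok)) {
    # parameters loading on the null space are non-identifiable
    null_load <- rowSums(abs(sv$v[, !ok, drop = FALSE]))
    ident <- null_load < 1e-6
    warn(sprintf("Jacobian is rank-deficient; non-identifiable: %s.",
                 paste(names(est)[!ident], collapse = ", ")))
  } else {
    ident <- rep(TRUE, k)
  }
  if (any(ident)) {
    vinv <- sv$v[, ok, drop = FALSE] %*%
      diag(1 / sv$d[ok]^2, sum(ok)) %*% t(sv$v[, ok, drop = FALSE])
    se[ident] <- sqrt(pmax(sigma2 * diag(vinv)[ident], 0))
  }
  se
}

#' Fit both lag variants and keep the AIC-preferred one
#'
#' Fits the complete model (with a lag parameter `log10_c0`) and the
#' reduced, no-lag model (`C0` fixed at 1e8) to the same dataset and
#' returns the fit with the lower AIC. On an exact AIC tie the reduced
#' model wins by parsimony. The lag fit is additionally restarted from the
#' no-lag solution so the nested-model property (complete RSS <= reduced
#' RSS) holds. The returned fit carries the comparison table in
#' `$comparison` and the losing AIC in `$aic_alternative`.
#'
#' @inheritParams fit_one_step
#' @param secondary_form Secondary-model form shared by both variants.
#' @param has_stationary Include a stationary phase in both variants?
#' @param quiet Suppress the AIC-decision message?
#'
#' @return A `growth_fit` (see [fit_one_step()]).
#' @export
select_variant <- function(data, secondary_form = c("sqrt", "linear"),
                           has_stationary = TRUE,
                           censoring = c("drop", "substitute"),
                           detection_limit = NULL, n_starts = 1, seed = 1L,
                           quiet = FALSE) {
  secondary_form <- match.arg(secondary_form)
  censoring <- match.arg(censoring)
  v_nolag <- model_variant(has_lag = FALSE, has_stationary = has_stationary,
                           secondary_form = secondary_form)
  v_lag <- model_variant(has_lag = TRUE, has_stationary = has_stationary,
                         secondary_form = secondary_form)

  fit_nolag <- tryCatch(
    fit_one_step(data, v_nolag, censoring = censoring,
                 detection_limit = detection_limit,
                 n_starts = n_starts, seed = seed),
    error = function(e) e
  )

  # lag fit: default start, plus a warm start at the no-lag solution with an
  # (effectively) vanishing lag, so the complete model nests the reduced one
  lag_starts <- list(NULL)
  if (inherits(fit_nolag, "growth_fit")) {
    warm <- fit_nolag$estimates
    lag_starts <- c(lag_starts, list(growth_params(
      log10_n0 = warm[["log10_n0"]], b = warm[["b"]], t_min = warm[["t_min"]],
      log10_nmax = if (has_stationary) warm[["log10_nmax"]] else NA_real_,
      log10_c0 = 7.5
    )))
  }
  fit_lag <- NULL
  lag_err <- NULL
  for (st in lag_starts) {
    f <- tryCatch(
      fit_one_step(data, v_lag, start = st, censoring = censoring,
                   detection_limit = detection_limit,
                   n_starts = n_starts, seed = seed),
      error = function(e) e
    )
    if (inherits(f, "growth_fit")) {
      if (is.null(fit_lag) || f$rss < fit_lag$rss) fit_lag <- f
    } else {
      lag_err <- f
    }
  }

  ok_nolag <- inherits(fit_nolag, "growth_fit") && fit_nolag$converged
  ok_lag <- !is.null(fit_lag) && fit_lag$converged
  if (!ok_nolag && !ok_lag) {
    abort(paste0(
      "Neither variant converged. no-lag: ",
      if (inherits(fit_nolag, "growth_fit")) fit_nolag$message
      else conditionMessage(fit_nolag),
      " | lag: ",
      if (!is.null(fit_lag)) fit_lag$message
      else if (!is.null(lag_err)) conditionMessage(lag_err) else "failed"
    ))
  }

  if (ok_nolag && ok_lag) {
    comparison <- tibble::tibble(
      variant = c("lag", "no_lag"),
      aic = c(fit_lag$aic, fit_nolag$aic),
      rss = c(fit_lag$rss, fit_nolag$rss),
      n_params = c(fit_lag$n_params, fit_nolag$n_params)
    )
    # tie goes to the reduced (no-lag) model by parsimony
    best <- if (fit_lag$aic < fit_nolag$aic) fit_lag else fit_nolag
    other <- if (identical(best, fit_lag)) fit_nolag else fit_lag
  } else {
    best <- if (ok_lag) fit_lag else fit_nolag
    other <- NULL
    comparison <- tibble::tibble(
      variant = if (ok_lag) "lag" else "no_lag",
      aic = best$aic, rss = best$rss, n_params = best$n_params
    )
  }
  best$comparison <- comparison
  best$aic_alternative <- if (!is.null(other)) other$aic else NA_real_
  if (!quiet) {
    inform(sprintf(
      "AIC selection: %s variant kept (AIC = %.2f%s).",
      if (best$variant$has_lag) "lag" else "no-lag", best$aic,
      if (!is.null(other)) sprintf(", alternative = %.2f", other$aic) else ""
    ))
  }
  best
}

.param_table <- function(x) {
  if (inherits(x, "growth_fit")) return(tidy(x))
  x <- as.data.frame(x)
  need <- c("term", "estimate", "std.error")
  if (!all(need %in% names(x))) {
    abort("Parameter tables need columns `term`, `estimate`, `std.error`.")
  }
  x[, need]
}

#' Compare parameter estimates between two fits (z-test)
#'
#' For each parameter shared by the two fits, computes
#' `z = (a - b) / sqrt(se_a^2 + se_b^2)` against a two-sided standard
#' normal reference, the standard large-sample comparison of regression
#' estimates from independent fits (e.g. control vs active packaging).
#'
#' @param fit_a,fit_b `growth_fit` objects, or data frames with columns
#'   `term`, `estimate`, `std.error` (so published estimate tables can be
#'   compared directly).
#' @param alpha Significance level for the `significant` flag.
#'
#' @return A tibble with one row per shared parameter: estimates, standard
#'   errors, `statistic`, `p.value` and `significant`. Parameters present in
#'   only one fit are dropped with a message.
#' @export
compare_parameters <- function(fit_a, fit_b, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  a <- .param_table(fit_a)
  b <- .param_table(fit_b)
  shared <- intersect(a$term, b$term)
  omitted <- setdiff(union(a$term, b$term), shared)
  if (length(omitted) > 0) {
    inform(sprintf("Not shared by both fits, omitted: %s.",
                   paste(omitted, collapse = ", ")))
  }
  a <- a[match(shared, a$term), ]
  b <- b[match(shared, b$term), ]
  delta <- a$estimate - b$estimate
  pooled <- sqrt(a$std.error^2 + b$std.error^2)
  z <- ifelse(delta == 0, 0, delta / pooled)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    term = shared,
    estimate_a = a$estimate, estimate_b = b$estimate,
    std_error_a = a$std.error, std_error_b = b$std.error,
    statistic = z, p.value = p,
    significant = p < alpha
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> one-step Baranyi-Ratkowsky fit\n")
  cat(sprintf("  variant: %s lag, %s stationary, %s secondary\n",
              if (x$variant$has_lag) "with" else "no",
              if (x$variant$has_stationary) "with" else "no",
              x$variant$secondary_form))
  cat(sprintf("  n = %d (censored handled: %s, %d flagged) | RSS = %.4g | AIC = %.2f\n",
              x$n_obs, x$censoring, x$n_censored, x$rss, x$aic))
  cat(sprintf("  converged: %s (%d iterations)\n", x$converged, x$n_iterations))
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_one_step
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors[names(x$estimates)])
  )
}

#' @rdname fit_one_step
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs, n_params = x$n_params, rss = x$rss,
    sigma = sqrt(x$rss / max(x$n_obs - x$n_params, 1)),
    AIC = x$aic, converged = x$converged, n_iterations = x$n_iterations,
    has_lag = x$variant$has_lag, has_stationary = x$variant$has_stationary,
    secondary_form = x$variant$secondary_form
  )
}

#' @rdname fit_one_step
#' @method augment growth_fit
#' @export
augment.growth_fit <- function(x, data = NULL, ...) {
  data <- data %||% x$data
  fitted <- predict_log_count(x$params, x$variant, data$temperature, data$time)
  dplyr::mutate(tibble::as_tibble(data),
                .fitted = fitted, .resid = .data$log10_count - fitted)
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  predict_log_count(object$params, object$variant,
                    newdata$temperature, newdata$time)
}
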