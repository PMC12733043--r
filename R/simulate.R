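# Seeded generators emulating the storage-trial design: noisy growth curves
# with a plate-count detection limit, and coupled quality tables for the
# correlation/regression stage.

#' Storage-trial design for a product
#'
#' Returns the storage design used throughout the package's simulations:
#' cherry tomatoes stored at 10, 15 and 22 degC with sampling up to 15, 14
#' and 8 days; kale stored at 2, 8, 15 and 22 degC with sampling up to 21,
#' 16, 9 and 7 days. Per-temperature sampling-day grids follow the trial's
#' quality-sampling schedule, and the typical initial loads per microbial
#' group are included (moulds on tomato start below the 2 log CFU/g
#' detection limit).
#'
#' @param product `"tomato"` or `"kale"`.
#'
#' @return A list with elements `product`, `temperatures` (degC),
#'   `sampling_days` (named list of day grids, one per temperature) and
#'   `initial_loads` (named vector, log10 CFU/g).
#' @examples
#' default_design("tomato")$sampling_days
#' @export
default_design <- function(product = c("tomato", "kale")) {
  if (!is.character(product) || length(product) != 1L ||
      !product %in% c("tomato", "kale")) {
    abort("Unknown product; must be \"tomato\" or \"kale\".")
  }
  if (product == "tomato") {
    list(
      product = "tomato",
      temperatures = c(10, 15, 22),
      sampling_days = list(
        `10` = c(0, 4, 8, 10, 15),
        `15` = c(0, 3, 7, 9, 14),
        `22` = c(0, 1, 2, 5, 8)
      ),
      initial_loads = c(mesophiles = 2.85, psychrophiles = 3.03,
                        enterobacteria = 2.95, yeasts = 3.02, moulds = 1.95)
    )
  } else {
    list(
      product = "kale",
      temperatures = c(2, 8, 15, 22),
      sampling_days = list(
        `2` = c(0, 3, 8, 11, 15, 21),
        `8` = c(0, 2, 7, 10, 14, 16),
        `15` = c(0, 2, 4, 7, 9),
        `22` = c(0, 1, 2, 3, 4, 7)
      ),
      initial_loads = c(mesophiles = 3.11, psychrophiles = 3.41,
                        enterobacteria = 2.01, moulds = 2.15, yeasts = 2.40)
    )
  }
}

#' Published one-step parameter estimates for tomato and kale
#'
#' Parameter estimates (with standard errors) of the Baranyi-Ratkowsky
#' model for the growth of five microbial groups on cherry tomatoes and
#' kale under control and active (essential-oil) paper packaging. These
#' serve as realistic ground-truth parameter sets for the package's
#' simulation studies. `has_lag = FALSE` rows correspond to conditions where
#' model selection preferred the no-lag variant; `has_stationary = FALSE`
#' marks the one condition that never reached a stationary phase.
#'
#' @return A tibble with one row per product x microorganism x packaging
#'   condition: estimates (`t_min`, `b`, `log10_n0`, `log10_nmax`,
#'   `log10_c0`), their standard errors (`*_se`), and the variant flags.
#' @examples
#' reference_growth_params() |>
#'   dplyr::filter(product == "kale", microorganism == "mesophiles")
#' @export
reference_growth_params <- function() {
  tbl <- tibble::tribble(
    ~product, ~microorganism, ~packaging, ~t_min, ~t_min_se, ~b, ~b_se,
    ~log10_n0, ~log10_n0_se, ~log10_nmax, ~log10_nmax_se, ~log10_c0, ~log10_c0_se,
    "tomato", "mesophiles", "active", 11.3, 0.69, 0.16, 0.03, 2.22, 0.09, 4.84, 0.24, NA, NA,
    "tomato", "mesophiles", "control", 6.65, 1.16, 0.10, 0.01, 2.39, 0.15, 5.65, 0.29, NA, NA,
    "tomato", "enterobacteria", "active", 10.27, 0.73, 0.11, 0.01, 2.22, 0.06, 4.50, 0.16, NA, NA,
    "tomato", "enterobacteria", "control", 10.75, 0.51, 0.14, 0.01, 2.40, 0.08, 6.49, 0.20, NA, NA,
    "tomato", "yeasts", "active", -4.36, 4.66, 0.04, 0.01, 2.32, 0.14, 5.14, 0.96, 0.49, 2.6,
    "tomato", "yeasts", "control", -1.09, 3.36, 0.05, 0.01, 2.38, 0.15, 5.53, 0.52, NA, NA,
    "tomato", "moulds", "active", -3.66, 1.57, 0.04, 0.01, 1.95, 0.03, 3.71, 0.10, 1.34, 0.4,
    "tomato", "moulds", "control", -9.41, 6.58, 0.03, 0.01, 2.00, 0.11, 4.59, 0.81, NA, NA,
    "tomato", "psychrophiles", "active", 19.76, 0.01, 0.58, 0.01, 2.60, 0.12, NA, NA, NA, NA,
    "tomato", "psychrophiles", "control", 8.51, 0.96, 0.11, 0.01, 2.58, 0.13, 7.85, 0.46, NA, NA,
    "kale", "mesophiles", "active", -3.47, 0.88, 0.11, 0.01, 3.43, 0.18, 7.48, 0.31, NA, NA,
    "kale", "mesophiles", "control", -4.99, 0.93, 0.10, 0.01, 3.48, 0.17, 7.75, 0.18, NA, NA,
    "kale", "enterobacteria", "active", -4.59, 0.38, 0.18, 0.01, 2.78, 0.14, 8.29, 0.23, NA, NA,
    "kale", "enterobacteria", "control", -3.47, 0.62, 0.13, 0.01, 2.25, 0.17, 7.53, 0.19, NA, NA,
    "kale", "yeasts", "active", -7.81, 1.09, 0.07, 0.01, 2.66, 0.12, 6.79, 0.16, NA, NA,
    "kale", "yeasts", "control", -6.10, 0.78, 0.10, 0.01, 2.62, 0.11, 6.64, 0.12, NA, NA,
    "kale", "moulds", "active", -1.84, 0.86, 0.06, 0.01, 2.53, 0.10, 7.33, 0.38, -0.35, 0.51,
    "kale", "moulds", "control", -4.30, 1.04, 0.06, 0.01, 2.57, 0.11, 7.52, 0.41, NA, NA,
    "kale", "psychrophiles", "active", -2.92, 1.03, 0.07, 0.01, 3.92, 0.13, 8.58, 0.26, NA, NA,
    "kale", "psychrophiles", "control", 2.59, 0.67, 0.12, 0.01, 4.32, 0.15, 9.97, 0.30, NA, NA
  )
  dplyr::mutate(tbl,
                has_lag = !is.na(.data$log10_c0),
                has_stationary = !is.na(.data$log10_nmax))
}

#' Extract one reference condition as parameters, variant and SE table
#'
#' Convenience accessor for [reference_growth_params()]: returns the chosen
#' condition as ready-to-use [growth_params()] and [model_variant()]
#' objects plus a `term`/`estimate`/`std.error` table usable with
#' [compare_parameters()].
#'
#' @param product,microorganism,packaging Condition selectors.
#' @param secondary_form Secondary form stored on the returned variant.
#'
#' @return A list with `params`, `variant` and `table`.
#' @examples
#' reference_condition("kale", "mesophiles", "control")$params
#' @export
reference_condition <- function(product, microorganism, packaging,
                                secondary_form = c("sqrt", "linear")) {
  secondary_form <- match.arg(secondary_form)
  row <- dplyr::filter(reference_growth_params(),
                       .data$product == !!product,
                       .data$microorganism == !!microorganism,
                       .data$packaging == !!packaging)
  if (nrow(row) != 1L) {
    abort("No such condition in the reference parameter table.")
  }
  params <- growth_params(
    log10_n0 = row$log10_n0, b = row$b, t_min = row$t_min,
    log10_nmax = row$log10_nmax, log10_c0 = row$log10_c0
  )
  variant <- model_variant(has_lag = row$has_lag,
                           has_stationary = row$has_stationary,
                           secondary_form = secondary_form)
  est <- c(log10_n0 = row$log10_n0, b = row$b, t_min = row$t_min,
           log10_nmax = row$log10_nmax, log10_c0 = row$log10_c0)
  se <- c(log10_n0 = row$log10_n0_se, b = row$b_se, t_min = row$t_min_se,
          log10_nmax = row$log10_nmax_se, log10_c0 = row$log10_c0_se)
  keep <- !is.na(est)
  list(
    params = params, variant = variant,
    table = tibble::tibble(term = names(est)[keep],
                           estimate = unname(est[keep]),
                           std.error = unname(se[keep]))
  )
}

#' Simulate a growth dataset under the storage-trial design
#'
#' Draws plate counts as the deterministic Baranyi-Ratkowsky prediction
#' plus additive Gaussian noise on the log10 scale. Values below the
#' detection limit are clamped to it and flagged as left-censored, matching
#' how plate counts below the limit of detection are recorded. The default
#' noise (sigma = 0.3 log10 units) and 3 replicates per point reflect
#' typical plate-count repeatability in storage trials.
#'
#' @param params A [growth_params()] object (the generating truth).
#' @param variant A [model_variant()].
#' @param design A design list as returned by [default_design()], or any
#'   list with `temperatures` and `sampling_days`.
#' @param replicates Replicates per temperature x day point.
#' @param noise_sd Standard deviation of the additive log10 noise.
#' @param detection_limit Detection limit, log10 CFU/g.
#' @param seed Integer seed; the generator draws all its noise from one
#'   stream seeded here, so equal seeds give identical datasets.
#' @param microorganism,packaging Labels stored on the dataset.
#'
#' @return A tibble with columns `product`, `microorganism`, `packaging`,
#'   `temperature`, `time`, `log10_count`, `censored`, and a
#'   `detection_limit` attribute. Accepted directly by [fit_one_step()] and
#'   [select_variant()].
#' @examples
#' p <- growth_params(2.4, b = 0.1, t_min = -5, log10_nmax = 7.8)
#' simulate_growth_dataset(p, seed = 1)
#' @export
simulate_growth_dataset <- function(params, variant = model_variant(),
                                    design = default_design("tomato"),
                                    replicates = 3, noise_sd = 0.3,
                                    detection_limit = 2, seed = 1L,
                                    microorganism = "mesophiles",
                                    packaging = "control") {
  stopifnot(inherits(params, "growth_params"), inherits(variant, "model_variant"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  days <- design$sampling_days
  if (any(vapply(days, function(d) is.unsorted(d) || any(d < 0), logical(1)))) {
    abort("`sampling_days` must be sorted and non-negative.")
  }

  grid <- purrr::map2_dfr(design$temperatures, days[as.character(design$temperatures)],
                          function(temp, dd) {
                            tidyr::expand_grid(temperature = temp, time = dd,
                                               replicate = seq_len(replicates))
                          })
  mean_log <- predict_log_count(params, variant, grid$temperature, grid$time)
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, noise_sd))
  obs <- mean_log + noise
  censored <- obs < detection_limit
  obs[censored] <- detection_limit

  out <- tibble::tibble(
    product = design$product %||% "unknown",
    microorganism = microorganism,
    packaging = packaging,
    temperature = grid$temperature,
    time = grid$time,
    log10_count = obs,
    censored = censored
  )
  attr(out, "detection_limit") <- detection_limit
  out
}

#' Simulate a quality table with a linear carotenoid-colour coupling
#'
#' Generates the statistical structure used by the correlation/regression
#' stage: colour-index values drawn uniformly on a range, carotenoid
#' content linear in the colour index plus Gaussian noise, and a firmness
#' column that decreases monotonically with the colour index (riper fruit
#' is softer), so rank-based checks have a known sign.
#'
#' @param n_samples Number of rows (>= 3).
#' @param ci_range Colour-index interval sampled uniformly.
#' @param slope,intercept Carotenoid-vs-colour-index coefficients
#'   (mg/kg per colour-index unit; mg/kg).
#' @param noise_sd Carotenoid noise standard deviation, mg/kg.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `sample_id`, `colour_index`,
#'   `carotenoids`, `firmness`.
#' @examples
#' simulate_quality_dataset(26, seed = 1)
#' @export
simulate_quality_dataset <- function(n_samples = 26, ci_range = c(17, 45),
                                     slope = 0.8, intercept = 40,
                                     noise_sd = 3, seed = 1L) {
  if (n_samples < 3) abort("`n_samples` must be >= 3.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (diff(range(ci_range)) == 0 && n_samples > 1) {
    abort("`ci_range` has zero width; colour index would be constant.")
  }
  withr::with_seed(seed, {
    ci <- runif(n_samples, min(ci_range), max(ci_range))
    caro <- intercept + slope * ci + rnorm(n_samples, 0, noise_sd)
  })
  rel <- (ci - min(ci_range)) / diff(range(ci_range))
  tibble::tibble(
    sample_id = seq_len(n_samples),
    colour_index = ci,
    carotenoids = caro,
    firmness = 16.3 - 12 * rel^1.5
  )
}
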