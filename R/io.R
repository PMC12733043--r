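# CSV / JSON readers and writers shared by the simulation and fitting
# stages, so simulated and real growth tables are interchangeable.

.growth_csv_cols <- c("product", "microorganism", "packaging",
                      "temperature_C", "time_days", "log10_count", "censored")

#' Read a long-format growth CSV into per-condition datasets
#'
#' Expects the schema `product, microorganism, packaging, temperature_C,
#' time_days, log10_count, censored` (comma-separated, `.` decimal, UTF-8,
#' header required) and returns one dataset per product x microorganism x
#' packaging condition, ready for [fit_one_step()] / [select_variant()].
#'
#' @param path CSV file path.
#' @param detection_limit Detection limit attached to every dataset,
#'   log10 CFU/g.
#'
#' @return A named list of tibbles (names `product/microorganism/packaging`)
#'   with columns `product`, `microorganism`, `packaging`, `temperature`,
#'   `time`, `log10_count`, `censored`.
#' @export
read_growth_csv <- function(path, detection_limit = 2) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    product = readr::col_character(),
    microorganism = readr::col_character(),
    packaging = readr::col_character(),
    temperature_C = readr::col_double(),
    time_days = readr::col_double(),
    log10_count = readr::col_double(),
    censored = readr::col_logical()
  ), show_col_types = FALSE)

  missing_cols <- setdiff(.growth_csv_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Growth CSV is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed growth CSV: row %d, column %d (%s).",
                  probs$row[1], probs$col[1], probs$expected[1]))
  }
  if (nrow(raw) == 0) abort("Growth CSV contains no observations.")
  if (any(!stats::complete.cases(raw))) {
    abort(sprintf("Growth CSV has missing values (first at row %d).",
                  which(!stats::complete.cases(raw))[1]))
  }

  raw <- dplyr::rename(raw, temperature = "temperature_C", time = "time_days")
  split_keys <- interaction(raw$product, raw$microorganism, raw$packaging,
                            sep = "/", drop = TRUE)
  lapply(split(raw, split_keys), function(d) {
    d <- tibble::as_tibble(d)
    attr(d, "detection_limit") <- detection_limit
    d
  })
}

#' Write a growth dataset to the long-format CSV schema
#'
#' Inverse of [read_growth_csv()]; a written-then-read dataset is
#' identical up to floating-point printing (full precision is kept).
#'
#' @param data A growth dataset tibble (as produced by
#'   [simulate_growth_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path) {
  need <- c("product", "microorganism", "packaging", "temperature", "time",
            "log10_count", "censored")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(setdiff(need, names(data)), collapse = ", ")))
  }
  out <- dplyr::select(tibble::as_tibble(data), dplyr::all_of(need))
  out <- dplyr::rename(out, temperature_C = "temperature", time_days = "time")
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a one-step fit as JSON
#'
#' Writes the fit with the conventional parameter symbols as keys
#' (`logN0`, `logNmax`, `b`, `Tmin`, `logC0`), their standard errors under
#' `se`, plus `AIC`, `RSS`, `n`, the variant flags and convergence
#' diagnostics.
#'
#' @param fit A `growth_fit` object.
#' @param path Output JSON path; when `NULL` the list is returned instead
#'   of written.
#' @return The JSON-ready list, invisibly when written.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  symbol <- c(log10_n0 = "logN0", log10_nmax = "logNmax", b = "b",
              t_min = "Tmin", log10_c0 = "logC0")
  est <- as.list(setNames(unname(fit$estimates), symbol[names(fit$estimates)]))
  se <- as.list(setNames(unname(fit$std_errors), symbol[names(fit$std_errors)]))
  out <- c(est, list(
    se = se,
    AIC = fit$aic,
    RSS = fit$rss,
    n = fit$n_obs,
    n_params = fit$n_params,
    has_lag = fit$variant$has_lag,
    has_stationary = fit$variant$has_stationary,
    secondary_form = fit$variant$secondary_form,
    converged = fit$converged,
    n_iterations = fit$n_iterations
  ))
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}
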