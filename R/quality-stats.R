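# Rank-correlation exploration of quality tables and the linear
# colour-index -> carotenoid prediction model.

#' Spearman correlation matrix of quality variables
#'
#' Spearman's rho (Pearson correlation of mean ranks, ties averaged) for
#' every pair of the selected numeric columns, with pairwise-complete
#' handling of missing values. Spearman is preferred over Pearson for
#' quality tables because it is invariant under monotone transforms and so
#' robust to the non-linear trajectories quality attributes follow during
#' storage.
#'
#' @param data A data frame of quality measurements.
#' @param columns Optional character vector of columns to correlate;
#'   defaults to all numeric columns.
#'
#' @return A symmetric correlation matrix (unit diagonal). Pairs involving
#'   a constant column are `NA`, with a warning.
#' @examples
#' q <- simulate_quality_dataset(20, seed = 1)
#' spearman_matrix(q, c("colour_index", "carotenoids", "firmness"))
#' @export
spearman_matrix <- function(data, columns = NULL) {
  data <- as.data.frame(data)
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Columns not found: %s.", paste(missing_cols, collapse = ", ")))
  }
  x <- data[, columns, drop = FALSE]
  if (length(columns) < 2L) abort("Need at least two columns to correlate.")
  for (i in seq_along(columns)) {
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      if (sum(ok) < 3L) {
        abort(sprintf("Fewer than 3 pairwise-complete rows for %s / %s.",
                      columns[i], columns[j]))
      }
    }
  }
  constant <- vapply(x, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) < 2L
  }, logical(1))
  if (any(constant)) {
    warn(sprintf("Constant column(s): %s; their correlations are NA.",
                 paste(columns[constant], collapse = ", ")))
  }
  m <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  diag(m) <- ifelse(constant, NA_real_, 1)
  m
}

#' Linear prediction of carotenoid content from the colour index
#'
#' Ordinary least-squares line predicting carotenoid content (mg/kg fresh
#' weight) from the tomato colour index, the basis for non-destructive
#' ripeness assessment: the colour index is measured with a colourimeter
#' while carotenoid quantification destroys the fruit.
#'
#' @param data A data frame containing the two variables.
#' @param ci_col,carotenoid_col Column names (default `"colour_index"`,
#'   `"carotenoids"`).
#'
#' @return An object of class `carotenoid_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n` and the underlying `lm` in `$model`.
#'   Methods: [tidy()], [glance()], `predict()` (takes colour-index values),
#'   `print()`, [autoplot()].
#' @examples
#' q <- simulate_quality_dataset(26, seed = 1)
#' fit <- fit_carotenoid_regression(q)
#' glance(fit)
#' predict(fit, colour_index = c(20, 40))
#' @export
fit_carotenoid_regression <- function(data, ci_col = "colour_index",
                                      carotenoid_col = "carotenoids") {
  data <- as.data.frame(data)
  if (!all(c(ci_col, carotenoid_col) %in% names(data))) {
    abort(sprintf("`data` needs columns `%s` and `%s`.", ci_col, carotenoid_col))
  }
  d <- data.frame(ci = data[[ci_col]], caro = data[[carotenoid_col]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3L) abort("Need >= 3 complete (colour index, carotenoid) pairs.")
  if (var(d$ci) == 0) abort("Colour index has zero variance; slope undefined.")

  model <- lm(caro ~ ci, data = d)
  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((d$caro - mean(d$caro))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(coef(model)[2]),
      intercept = unname(coef(model)[1]),
      r_squared = r2,
      n = nrow(d),
      ci_col = ci_col,
      carotenoid_col = carotenoid_col,
      model = model,
      data = tibble::as_tibble(d)
    ),
    class = "carotenoid_fit"
  )
}

#' @export
print.carotenoid_fit <- function(x, ...) {
  cat("<carotenoid_fit> carotenoids ~ colour index\n")
  cat(sprintf("  carotenoids = %.3f + %.3f * %s  (R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$ci_col, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_carotenoid_regression
#' @param x A `carotenoid_fit` object.
#' @param ... Unused.
#' @method tidy carotenoid_fit
#' @export
tidy.carotenoid_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_carotenoid_regression
#' @method glance carotenoid_fit
#' @export
glance.carotenoid_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n,
                 sigma = summary(x$model)$sigma)
}

#' @export
predict.carotenoid_fit <- function(object, colour_index = NULL, ...) {
  colour_index <- colour_index %||% object$data$ci
  object$intercept + object$slope * colour_index
}
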