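# CIELab colour indices and spectrophotometric pigment equations.

#' CIELab colour indices
#'
#' Appends the five colour indices used in postharvest quality work to a
#' table of CIELab readings: chroma `sqrt(a^2 + b^2)`, hue angle (degrees,
#' two-argument arctangent mapped to \[0, 360) so green produce with
#' negative `a` lands near 128 rather than in the wrong quadrant), the
#' tomato colour index `2000 a / (L * chroma)`, the yellowness index
#' `coef * b / L`, and the total colour difference from a day-0 reference
#' `sqrt(dL^2 + da^2 + db^2)`.
#'
#' The yellowness-index coefficient defaults to the standard 142.86; the
#' alternative convention 14.286 found in some sources can be selected via
#' `yi_coefficient`.
#'
#' @param data Data frame with columns `L`, `a`, `b` (CIELab readings,
#'   one row per measurement).
#' @param reference Optional day-0 reference: a list, named vector or
#'   one-row data frame with `L`, `a`, `b`. When omitted the total colour
#'   difference is `NA`.
#' @param yi_coefficient Yellowness-index coefficient (142.86 or 14.286).
#'
#' @return The input as a tibble with columns `chroma`, `hue`,
#'   `colour_index`, `yellowness_index`, `total_colour_difference` added.
#' @examples
#' tomato_day0 <- data.frame(L = 60.9, a = 51.8, b = 82.1)
#' compute_colour_indices(tomato_day0)
#' @export
compute_colour_indices <- function(data, reference = NULL,
                                   yi_coefficient = 142.86) {
  data <- tibble::as_tibble(data)
  need <- c("L", "a", "b")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns `L`, `a`, `b`.")
  }
  if (any(!is.finite(data$L)) || any(data$L <= 0) || any(data$L > 100)) {
    abort("`L` must be finite and in (0, 100].")
  }
  if (any(!is.finite(data$a)) || any(!is.finite(data$b))) {
    abort("`a` and `b` must be finite.")
  }
  if (any(data$a == 0 & data$b == 0)) {
    abort("Hue and colour index are undefined when a = b = 0.")
  }

  chroma <- sqrt(data$a^2 + data$b^2)
  hue <- atan2(data$b, data$a) * 180 / pi
  hue <- hue %% 360
  ci <- 2000 * data$a / (data$L * chroma)
  yi <- yi_coefficient * data$b / data$L

  tcd <- rep(NA_real_, nrow(data))
  if (!is.null(reference)) {
    ref <- as.list(as.data.frame(as.list(reference)))
    if (!all(need %in% names(ref))) {
      abort("`reference` needs elements `L`, `a`, `b`.")
    }
    tcd <- sqrt((data$a - ref$a)^2 + (data$b - ref$b)^2 + (data$L - ref$L)^2)
  }

  dplyr::mutate(data, chroma = chroma, hue = hue, colour_index = ci,
                yellowness_index = yi, total_colour_difference = tcd)
}

#' Chlorophyll and carotenoid concentrations from extract absorbances
#'
#' Applies the linear spectrophotometric equations for hexane extracts:
#' `Ca = 10.05 A662 - 0.766 A644`, `Cb = 16.37 A644 - 3.14 A662` and
#' `carotenoids = (1000 A470 - 1.28 Ca - 56.7 Cb) / 205` (all ug/mL), then
#' converts to mg/kg on a fresh-weight basis by multiplying by the extract
#' volume over the sample mass. Computed concentrations below zero (possible
#' with noisy absorbances) are floored at zero with a warning.
#'
#' @param data Data frame with absorbance columns `a470`, `a662`, `a644`
#'   (case-insensitive, so `A470` etc. also work).
#' @param sample_mass_g Fresh sample mass extracted, g.
#' @param extract_volume_ml Hexane volume, mL.
#'
#' @return The input as a tibble with `chlorophyll_a_ug_ml`,
#'   `chlorophyll_b_ug_ml`, `carotenoids_ug_ml` and the corresponding
#'   `*_mg_kg` fresh-weight columns added.
#' @examples
#' compute_pigments(data.frame(a470 = 1.2, a662 = 0.8, a644 = 0.3))
#' @export
compute_pigments <- function(data, sample_mass_g = 2, extract_volume_ml = 3.6) {
  if (sample_mass_g <= 0) abort("`sample_mass_g` must be > 0.")
  if (extract_volume_ml <= 0) abort("`extract_volume_ml` must be > 0.")
  data <- tibble::as_tibble(data)
  lookup <- setNames(names(data), tolower(names(data)))
  need <- c("a470", "a662", "a644")
  if (!all(need %in% names(lookup))) {
    abort("`data` needs absorbance columns `a470`, `a662`, `a644`.")
  }
  a470 <- data[[lookup[["a470"]]]]
  a662 <- data[[lookup[["a662"]]]]
  a644 <- data[[lookup[["a644"]]]]
  if (any(c(a470, a662, a644) < 0)) abort("Absorbances must be >= 0.")

  ca <- unname(10.05 * a662 - 0.766 * a644)
  cb <- unname(16.37 * a644 - 3.14 * a662)
  caro <- unname((1000 * a470 - 1.28 * ca - 56.7 * cb) / 205)

  vals <- cbind(ca, cb, caro, deparse.level = 0)
  if (any(vals < 0)) {
    warn("Negative computed concentrations floored at 0.")
    vals[vals < 0] <- 0
  }
  fw <- extract_volume_ml / sample_mass_g
  dplyr::mutate(data,
                chlorophyll_a_ug_ml = vals[, 1],
                chlorophyll_b_ug_ml = vals[, 2],
                carotenoids_ug_ml = vals[, 3],
                chlorophyll_a_mg_kg = vals[, 1] * fw,
                chlorophyll_b_mg_kg = vals[, 2] * fw,
                carotenoids_mg_kg = vals[, 3] * fw)
}
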