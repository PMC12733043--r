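# Shared fixtures: all data are generated in code at test time.

# growth parameters with a lag that is clearly identifiable from the kale
# design (the lag costs ln(1 + 1/C0) = ln(11) ~ 2.4 log10 units of growth)
lagged_params <- function() {
  growth_params(log10_n0 = 3.5, b = 0.1, t_min = -5, log10_nmax = 8.5,
                log10_c0 = -1)
}

# build a baranyi curve's (params, variant, temperature) triple that
# realises a given (mu_max, lambda) pair, for direct closed-form/ODE checks
curve_for <- function(mu, lambda, log10_n0, log10_nmax) {
  log10_c0 <- if (lambda == 0) NA_real_ else log10(1 / expm1(mu * lambda))
  list(
    params = growth_params(log10_n0 = log10_n0, b = mu, t_min = 0,
                           log10_nmax = log10_nmax, log10_c0 = log10_c0),
    variant = model_variant(has_lag = lambda > 0, secondary_form = "linear"),
    temperature = 1
  )
}

# replicate seeds used by every stochastic check: one draw from a single
# base stream, the same discipline the acceptance script follows
replicate_seeds <- function(n, base = 1) {
  withr::with_seed(base, sample.int(1e6, n))
}

# brute-force Spearman rho for untied data: 1 - 6 sum(d^2) / (n (n^2 - 1))
spearman_bruteforce <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

quiet_select <- function(...) {
  suppressWarnings(suppressMessages(select_variant(..., quiet = TRUE)))
}

quiet_fit <- function(...) {
  suppressWarnings(fit_one_step(...))
}
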