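---
title: "One-step growth modelling and quality metrics for fresh produce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step growth modelling and quality metrics for fresh produce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freshfit)
library(dplyr)
```

## The model

freshfit analyses microbial shelf-life trials in which plate counts of one
microbial group are followed over storage time at several constant
temperatures, for one product under one packaging treatment. The primary
model is the Baranyi sigmoid, evaluated natively on the log10 scale:

$$\log_{10} N(t) = \log_{10} N_0 + \mu_{\max} A(t)
  - \log_{10}\!\left(1 + \frac{10^{\mu_{\max} A(t)} - 1}
  {10^{\log_{10} N_{\max} - \log_{10} N_0}}\right),$$

with the standard adjustment function
$A(t) = t + \tfrac{1}{\mu_{\max}}\log_{10}\!\left(10^{-\mu_{\max} t} +
10^{-\mu_{\max}\lambda} - 10^{-\mu_{\max}(t+\lambda)}\right)$ encoding the
lag. The Baranyi curve is invariant under the change of logarithm base as
long as the rate is rescaled, so working in log10 means every parameter is
read and reported directly in the units microbiologists use
(log CFU g^-1^, log CFU g^-1^ day^-1^).

Temperature enters through the sub-optimal Ratkowsky secondary model with
slope $b$ and theoretical minimum growth temperature $T_{\min}$:
$\sqrt{\mu_{\max}} = b\,(T - T_{\min})$ for $T > T_{\min}$ and
$\mu_{\max} = 0$ otherwise. The square-root form is the package default
because it is the form under which the companion lag relation is an
*inverse square-root* law (below); the linear form
$\mu_{\max} = b\,(T - T_{\min})$ remains selectable via
`model_variant(secondary_form = "linear")`, and generator and fitter always
share one form.

The lag phase is tied to the growth rate by the physiological-state
parameter $C_0$ through the constant-"work to be done" relation

$$\lambda(T) = \frac{\ln(1 + 1/C_0)}{\mu_{\max}(T)},$$

the unique lag secondary model compatible with the Baranyi primary model:
the product $\mu_{\max}\lambda$ is the same at every temperature. Under the
square-root form this makes $1/\sqrt{\lambda}$ linear in $(T - T_{\min})$
with coefficient $1/\sqrt{B}$, $B = \ln(1 + 1/C_0)/b^2$
(`lag_coefficient_b()`). Very large $C_0$ ($10^8$) means fully adapted
cells and no lag; the no-lag model variant is exactly this limit.

## One-step fitting

All curves of a condition are fitted **jointly**: the five parameters
($\log_{10} N_0$, $\log_{10} N_{\max}$, $b$, $T_{\min}$, $\log_{10} C_0$)
enter a single least-squares objective over every temperature at once,
rather than fitting each curve and regressing its parameters afterwards.
One-step fitting propagates information across temperatures and is markedly
more robust for sparse storage-trial data. Concentration-like parameters
are fitted on the log10 scale for identifiability.

Numerical choices:

* **Optimiser** — bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with a
  numeric Jacobian and a deterministic data-driven start
  (`initial_guesses()`); an optional seeded multistart (`n_starts`) is
  available for refractory datasets. The same data and start always return
  a bit-identical fit.
* **Bounds** — $b \in (0, 5]$, counts in $[0, 15]$ log CFU g^-1^,
  $\log_{10} C_0 \in [-5, 8]$ and $T_{\min} \in [-30, T_{\text{top}} - 0.1]$
  where $T_{\text{top}}$ is the warmest tested temperature. The upper
  $T_{\min}$ bound deliberately sits *above* the coldest tested temperature:
  conditions in which no growth occurs at the lower temperatures (observed
  here for enterobacteria and psychrophiles under active packaging) have
  their $T_{\min}$ between the tested temperatures, and clamping it below
  the coldest one would make those regimes unreachable.
* **Censoring** — plate counts below the detection limit (2 log CFU g^-1^
  by default) are left-censored. They are excluded from the residuals by
  default (`censoring = "drop"`), with substitution by the limit available
  (`censoring = "substitute"`). Neither choice is innocuous when the true
  initial load sits at the limit; see *Known limitations*.
* **"No stationary phase"** — conditions that never plateau are fitted with
  the ceiling fixed at 15 log CFU g^-1^ (`has_stationary = FALSE`),
  effectively unbounded within any observation window.
* **AIC selection** — the complete (lag) and reduced (no-lag) models are
  both fitted by `select_variant()` and compared with
  $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(k+1)$, the concentrated Gaussian
  form with the residual variance counted as a parameter; the small-sample
  AICc is not used. The lag fit is warm-started from the no-lag solution so
  the nested-model inequality (complete RSS $\le$ reduced RSS) holds; an
  exact AIC tie goes to the reduced model by parsimony.
* **Standard errors** — Gauss–Newton,
  $\widehat\sigma^2 (J^\top J)^{-1}$ with
  $\widehat\sigma^2 = \mathrm{RSS}/(n-k)$. A singular-value rank check on
  $J$ flags non-identifiable parameters as `NA` instead of reporting a
  meaningless number — this happens, for instance, when growth was observed
  at a single temperature so only the product $b\,(T - T_{\min})$ is
  constrained.
* **Treatment comparison** — `compare_parameters()` uses
  $z = (\theta_A - \theta_B)/\sqrt{SE_A^2 + SE_B^2}$ against a two-sided
  standard normal. A normal rather than a finite-df t reference is used
  because no degrees-of-freedom convention is available for published
  estimate tables; at the sample sizes involved the difference is
  immaterial.

## What the synthetic data emulate

`default_design()` reproduces the storage layout of a cherry tomato / kale
trial: tomatoes at 10, 15 and 22 °C sampled on days {0, 4, 8, 10, 15},
{0, 3, 7, 9, 14} and {0, 1, 2, 5, 8}; kale at 2, 8, 15 and 22 °C sampled on
days {0, 3, 8, 11, 15, 21}, {0, 2, 7, 10, 14, 16}, {0, 2, 4, 7, 9} and
{0, 1, 2, 3, 4, 7}. Initial loads per microbial group are the trial's
day-0 plate counts (moulds on tomato start below the detection limit).
`simulate_growth_dataset()` adds Gaussian noise on the log10 scale
(default $\sigma = 0.3$, typical plate-count repeatability; the trials'
true replicate error is not recoverable, so $\sigma$ is a configuration
knob, not a claim) with 3 replicates per point, clamps values below the
detection limit to it and flags them censored. All randomness flows through
one explicitly seeded stream per dataset.

The generator deliberately does **not** emulate within-package atmosphere
dynamics, essential-oil release kinetics, between-replicate batch effects,
or non-Gaussian plate-count error. Passing recovery tests therefore shows
that the estimation machinery is correct and well-calibrated under the
stated error model — not that real trials of this size always identify
every parameter.

`reference_growth_params()` ships the published one-step estimates for all
twenty product × microorganism × packaging conditions and is the ground
truth for the package's simulation studies; problem sizes used in the
shipped checks (20 seeded datasets per condition, 3 replicates,
$\sigma = 0.3$) mirror a realistic desk-scale power study.

## Colour and pigment arithmetic

`compute_colour_indices()` turns CIELab readings into chroma
$\sqrt{a^2+b^2}$, hue angle, the tomato colour index
$2000a/(L\cdot\mathrm{chroma})$, the yellowness index
$\mathrm{YI} = 142.86\,b/L$ and the total colour difference from a day-0
reference. Two conventions deserve a note:

* the hue uses the two-argument arctangent mapped to $[0, 360)$ — a
  quadrant-blind $\arctan(b/a)$ returns ≈ −52° for green kale
  ($a = -16.5$, $b = 21.0$), while the quadrant-aware angle is ≈ 128°,
  which is what the colour of green produce actually is;
* the yellowness coefficient defaults to the standard 142.86. The
  alternative 14.286 seen in some sources would give a day-0 kale YI of
  6.2, an order of magnitude below the values reported for leafy
  vegetables; it remains available as `yi_coefficient = 14.286`.

Indices are computed per reading and then averaged, not computed on
averaged Lab coordinates; the two differ slightly because the indices are
non-linear in $(L, a, b)$.

`compute_pigments()` applies the linear spectrophotometric equations for
chlorophyll a/b and total carotenoids in hexane extracts and converts
µg mL^-1^ to mg kg^-1^ fresh weight via the extract volume over sample mass
(defaults 3.6 mL / 2 g). Negative computed concentrations — possible with
noisy absorbances near zero — are floored at zero with a warning.

## Correlation and regression stage

`spearman_matrix()` computes Spearman's ρ (Pearson correlation of mean
ranks, ties averaged) with pairwise-complete deletion of missing values —
the package's choice where nothing else is specified — and flags constant
columns as `NA` rather than failing. `fit_carotenoid_regression()` is an
ordinary least-squares line predicting carotenoid content from the colour
index, the basis for non-destructive ripeness assessment; it exposes
broom-style `tidy()`/`glance()` and a prediction helper. Published
replicate-level correlations cannot be reproduced without the raw data, so
the shipped checks validate this stage on synthetic tables with known
coupling (including a noise level chosen analytically as
$\text{slope}\cdot\mathrm{SD(CI)}\cdot\sqrt{1/R^2 - 1}$ to land at a target
$R^2$).

## Worked example

```{r example}
rc <- reference_condition("kale", "mesophiles", "control")
d <- simulate_growth_dataset(rc$params, rc$variant,
                             design = default_design("kale"), seed = 1)
fit <- select_variant(d, quiet = TRUE)
tidy(fit)
glance(fit)
```

```{r compare}
active <- reference_condition("kale", "mesophiles", "active")$table
control <- reference_condition("kale", "mesophiles", "control")$table
compare_parameters(active, control)
```

## Known limitations

* **A physiologically plausible lag can be statistically invisible.** The
  lag shifts the whole curve by $\mu_{\max}\lambda = \ln(1 + 1/C_0)$ log10
  units at every temperature. For $\log_{10} C_0 = 1.34$ — the value
  reported for moulds under active packaging — that shift is ≈ 0.045 log10
  units, an order of magnitude below realistic plate-count noise
  ($\sigma = 0.3$). At desk scale, AIC selects the lag variant for such
  data only rarely, and when it does the recovered $\log_{10} C_0$ is
  essentially unconstrained. Lag detection by AIC is reliable only when
  $\ln(1 + 1/C_0)$ is comparable to or larger than the noise, i.e. for
  $C_0 \lesssim 1$.
* **Censoring at the detection limit interacts with model selection.** When
  the true initial load sits at or below the limit, dropping censored
  observations biases the earliest observed means upward, which mimics a
  lag and inflates spurious lag selections (substitution reduces but does
  not remove the effect). This is a property of the censoring treatment,
  not of the optimiser.
* $T_{\min}$ is an extrapolation of the secondary model, not an observed
  growth boundary; with growth at few temperatures its uncertainty is
  large, and with growth at a single temperature it is flagged
  non-identifiable outright.
* Dynamic (time-varying temperature) predictions, cardinal-parameter
  secondary models and inactivation kinetics are out of scope.
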