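---
title: "Methods: Bayesian Poisson GAMs for PM2.5, weather and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian Poisson GAMs for PM2.5, weather and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pmgam` implements a fully Bayesian time-series analysis of daily
non-accidental mortality against PM2.5 and weather. This vignette is
the package's account of the statistical choices behind it: the model
and its assumptions, what the synthetic-data generator does and does
not emulate, the numerical design of the sampler, and the known
limitations. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The regression model

The unit of analysis is the day-by-stratum cell: deaths among one
sex × age-group × occupation stratum on one calendar day, assumed
Poisson with log-linear rate

\[
\log E(Y_{t,s}) = \beta_0 + \beta_1\,\mathrm{PM}_{t} + \beta_2'W_t +
\beta_3'(\mathrm{PM}_t \times W_t) + \beta_4\,\mathrm{Sex}_s +
\beta_5'\mathrm{Age}_s + \beta_6'\mathrm{Job}_s + \beta_7'\mathrm{DOW}_t +
\beta_8\,\mathrm{Smoking}_s + S(t).
\]

Dummy coding uses the most populous groups as references (age 65+,
occupation Manufactory) except for sex (male) and day of week (Sunday);
the synoptic-type coding uses cold humid as reference. The model mixes
a daily count outcome with individual-level covariates; treating counts
per covariate stratum (with dummy-coded stratum effects and no
population offset) is the only coding under which this is a
well-defined Poisson regression, and it is what the generator and the
design builder both implement.

Two weather codings are supported. The **extreme-condition coding**
uses eight *non-exclusive* day-count flags: a day is hot/cold when its
max/min temperature is strictly beyond the pooled 90th/10th empirical
percentile (type-7, linear interpolation between order statistics) of
the whole study period, and analogously hyperbaria/hypobaria (max/min
pressure), humid/dry (mean humidity), windy/windless (mean wind speed).
Pooled thresholds — one per variable over the full period — are the
default because day-count indices are defined against a fixed reference
distribution and pooled quantiles are the more stable choice for a
three-year record; per-calendar-year thresholds are available via
`by_year = TRUE`. The model's `j = 8` flag block intentionally has no
reference category because the flags are not exclusive (the baseline is
"not extreme"). The **synoptic weather type (SWT) coding** standardizes
the 15 meteorological parameters, retains principal components to 93 %
cumulative variance (capped at six), clusters the scores with
best-of-25-restarts K-means, and names the six clusters by ranking the
centroids: split at the cross-centroid median humidity into three dry
and three humid types, then order each triple by temperature (hot /
moderate / cold dry; warm / moderate / cold humid). Ties are broken
deterministically by centroid pressure with a warning. The number of
clusters can be chosen by the elbow rule: the k maximizing the second
difference of the WSS curve, declared only when a smooth power-law
decay (log-log linear fit, R² < 0.97) fails to explain the curve —
structureless data therefore fall back to a configurable default with a
warning rather than inventing an elbow.

The smooth term \(S(t)\) is a cubic B-spline on calendar time mapped to
[0, 1], with interior knots equally spaced — 5 per year, hence 15
interior knots and a 19-column basis for a three-year study. Knot
placement is the package's choice (the knot count is the protocol's).
For identifiability next to the intercept the first basis column is
dropped and the remainder centred to zero mean; this changes only the
intercept's meaning.

## Priors

The default prior is Jeffreys' prior from the observed Fisher
information of the Poisson model,
\(\pi(\beta) \propto |X'W(\beta)X|^{1/2}\) with \(W = \mathrm{diag}(\mu)\),
implemented exactly in `log_prior_jeffreys()`. Spline coefficients
receive the same treatment as the fixed effects — the model makes no
distinction — and an informative independent normal prior
(`prior_spec("normal")`) is available for sensitivity analysis, e.g.
centring the PM2.5 slope at `log(1.0022)/10` per µg/m³ to encode a
published 0.22 % per-10-µg/m³ estimate.

Inside the Gibbs sampler the Jeffreys prior is handled by a **per-sweep
local linearization**: at the start of a sweep (every `refresh` sweeps,
default 10) the gradient of \(\tfrac12\log|X'WX|\) is evaluated at the
current state — coordinate j's slope is
\(\tfrac12\sum_i h_i \mu_i x_{ij}\) with \(h_i\) the leverages — and
enters each univariate conditional as a linear term. Evaluating the
exact log-determinant inside every rejection-sampling density call
would cost \(O(np^2)\) per evaluation and is not tractable at the
protocol's chain lengths; the linearization exploits precisely the
property that motivates this prior, its local uniformity (it changes
slowly where the likelihood is concentrated). The approximation is
validated in the test suite against the exact-prior posterior obtained
by numerical integration on an intercept model, and the linear term
keeps every full conditional log-concave, so the ARMS step remains an
exact rejection sampler.

## Sampling: ARMS within Gibbs in a decorrelated basis

Coordinates are updated sequentially from their univariate full
conditionals by adaptive rejection Metropolis sampling: a
piecewise-linear upper hull of the log conditional is built from
secants through five abscissae (current value ± 1 and ± 3 conditional
SDs), candidates are drawn from the corresponding piecewise
exponential, rejected candidates refine the hull, and every accepted
candidate passes a Metropolis–Hastings correction. For log-concave
targets — all conditionals of this model under its priors — the hull
dominates the density, the correction accepts with probability one and
the draws are exact; the correction is applied unconditionally so the
kernel stays valid for any target. Support is clipped to ±50 on the
sampled scale, and a chain aborts with a diagnostic if a coordinate
reaches the bound.

Naive single-site Gibbs mixes poorly here: the intercept, the
demographic dummies, the smoking slope and the spline block are
strongly correlated a posteriori. The sampler therefore works in a
**decorrelated parameterization**: after a Newton fit of the posterior
mode, all non-intercept columns are centred with the mode weights and
the day-level block (PM2.5, weather, interactions, DOW, spline) and the
stratum-level block (sex, age, occupation, smoking) are whitened by the
Cholesky factors of their blocks of the mode information matrix. For a
complete day-by-stratum crossing the weighted cross-moments between the
two blocks vanish, so the transformed information matrix is essentially
the identity and the Gibbs sweep mixes almost like independent
sampling. The map is invertible and linear, so the posterior is
unchanged; draws are transformed back to the coefficient scale before
anything else sees them. Crucially, each transformed column is still
constant within days (or strata), which preserves the grouped
evaluation of the Poisson likelihood — each conditional density call
costs O(#distinct column values), not O(rows) — and keeps the full
protocol (3 chains × 6000 sweeps on ~26,000 cells) at around two
minutes on one CPU in the compiled core.

Chains start at the posterior mode plus 2-SD Gaussian jitter
(overdispersed starts, so the Gelman–Rubin diagnostic is meaningful)
and use per-chain seeds feeding a dedicated Mersenne-Twister stream,
independent of R's RNG. The protocol defaults are burn-in 1000, 5000
retained iterations, thinning 10 (500 kept draws per chain), three
chains.

## Diagnostics

`gelman_rubin()` implements the classic PSRF with the
degrees-of-freedom adjustment and the 97.5 % sampling upper bound.
The bound is computed on the **unthinned** post-burn-in chains whenever
the sampler kept them (it does, below five million stored values):
thinning is a storage economy, and at 500 thinned draws the pure
estimator noise of a maximum over ~50 coefficients exceeds the 1.01
pass threshold even for perfectly mixed chains. Autocorrelations and
ESS are computed on the thinned chains that are actually summarized:
per-chain ACFs are averaged across chains per parameter (the standard
multi-chain estimator; it quarters the variance of a single-chain ACF),
ESS uses Geyer's initial-positive-sequence truncation with the monotone
adjustment, is capped at the number of kept draws, and efficiency is
ESS over kept draws. Pass rules follow the protocol: PSRF upper bound
< 1.01, |lag-5 ACF| < 0.1, pooled ESS > 1000, efficiency > 0.6.
Constant chains are flagged, not crashed. Model fit is checked by
Pearson residuals of the daily totals, \((Y_d - \hat\mu_d)/\sqrt{\hat\mu_d}\)
at the posterior-mean coefficients; under a well-specified model with
daily means in the hundreds these are nearly standard normal, so the
within-±2 fraction has expectation ≈ 0.954 and binomial noise of about
±0.6 percentage points at 1100 days — the acceptance test treats the
95 % threshold accordingly (a one-sided binomial consistency check
rather than a knife-edge comparison). Trace data are exported as tidy
draw tables (`run_pipeline()` writes per-variant CSVs); visual judgement
of trace plots is out of scope.

## Effect reporting

Draws of the PM2.5 slope (per µg/m³ internally) are transformed
per-draw to `100*(exp(10*beta) - 1)` and summarized by the posterior
mean and the empirical 2.5th/97.5th percentiles — transform first,
summarize after, which for equal-tail intervals coincides with
transforming the interval endpoints (monotone invariance; asserted in
the tests up to quantile interpolation). The effect of PM2.5 under a
given weather condition combines the main and interaction percent
increases multiplicatively,
`100*((1 + main/100)*(1 + inter/100) - 1)`; the additive shortcut
`main + inter` is reported alongside, and a second-order bound
guarantees the two agree to below 0.01 percentage points whenever both
inputs are under ~1.4 %, i.e. at the two-decimal precision of the
printed tables (half-up rounding). Four canonical model variants are
supported: {extreme, SWT} × {with, without interaction}, plus the
normal-prior sensitivity variant.

## The synthetic-data generator

The generator provides known-truth data with the statistical structure
the analysis assumes, not a reproduction of any real city's joint
weather distribution.

* **Calendar**: inclusive daily range (1096 days for 2012–2014),
  day-of-week factor, normalized time.
* **Meteorology**: 15 parameters (min/mean/max pressure and
  temperature, mean/min humidity, precipitation, five wind statistics,
  sunshine) driven by an annual cosine plus five latent AR(1) synoptic
  factors (autocorrelation 0.78) and small idiosyncratic AR(1) terms.
  Loadings were fixed once so that the standardized matrix is
  approximately rank six: six PCs explain ≥ 93 % of the variance and
  five do not, the dimensionality the synoptic-typing step assumes.
  Min/mean/max triplets are built as mean ± strictly positive gaps, so
  their ordering holds surely; humidity is clipped to [0, 100],
  precipitation is a thresholded latent (realistic dry-day mass),
  wind and sunshine are nonnegative.
* **PM2.5**: log-normal, log-mean coupled negatively (−0.5 per SD) to
  standardized daily mean temperature plus AR(1) log noise — cold
  season concentrations roughly double warm-season ones, matching the
  winter-high/summer-low pattern of urban monitoring records; exactly
  `n_missing` days (default 5) are flagged missing, placed in the first
  study year as in newly deployed monitors.
* **Deaths**: Poisson per day-stratum cell from the exact model above.
  The default truth uses a PM2.5 effect of 0.30 % per 10 µg/m³,
  weather and interaction effects of realistic few-percent magnitude,
  strong age/occupation contrasts, a ~2 %-per-point smoking slope, a
  winter-peaking cosine trend (amplitude 0.15), and an intercept
  calibrated once so the default 24 strata yield roughly 300 deaths per
  day. Smoking rate is assigned per sex-age cell with sex-level values
  near 29.7 % (men) and 0.9 % (women) and a plausible age gradient; a
  strictly sex-constant rate would be perfectly collinear with the sex
  dummy, so the gradient is what makes the smoking slope identifiable.
  Missing-PM days are dropped (complete case) by default.

Stage seeds derive deterministically from one master seed; identical
seeds give bit-identical outputs. What passing tests on these data show
is that the pipeline is *internally correct* — it recovers known
coefficients with nominal coverage and its diagnostics behave — not
that any epidemiological estimate transfers to real registries: real
mortality exhibits overdispersion, lagged exposure effects, monitor
measurement error and population drift that the generator deliberately
omits.

## Problem sizes used in the checks

The acceptance script fits the default three-year reduced-strata study
(~26,000 cells, ~50 coefficients) under the full 3 × (1000 + 5000)
protocol, and measures coverage over 50 replicates of a ~400-day
two-stratum design with a reduced run (2 chains, 200 + 1000, thin 5) —
sizes chosen so the whole suite is a desk-scale computation while the
main fit still runs the complete protocol.

## Known limitations

* No lag or distributed-lag exposure effects; same-day exposure only.
* Single pollutant; no cause-specific mortality.
* The Jeffreys prior inside the sampler is locally linearized per sweep
  (exact standalone evaluation is provided); with the data sizes used
  here the prior's influence on the posterior is negligible, but on
  very small data the approximation error could matter.
* The elbow rule's power-law null is a heuristic; for clustering
  structures far from spherical blobs the k choice should be inspected.
* Percent-increase reporting assumes the log-linear model scale;
  effects below −100 % are impossible by construction.
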