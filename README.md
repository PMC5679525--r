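# pmgam

Bayesian Poisson generalized additive models for time-series analysis of
daily non-accidental mortality against fine particulate matter (PM2.5)
and weather, with synoptic weather typing and extreme-weather day-count
indices.

`pmgam` is aimed at environmental epidemiologists who want a fully
Bayesian alternative to the usual quasi-Poisson GAM time-series analysis
of air-pollution mortality: every stage — weather feature construction,
model fitting by MCMC, convergence diagnostics, and percent-increase
reporting — is a tested, reusable function, and a calibrated
synthetic-data generator with known coefficient truth makes the whole
chain verifiable without access to confidential registry data.

## The model

Daily death counts per population stratum (sex × age group × occupation)
are Poisson with a log-linear rate:

```
log E(Y_t) = β0 + β1·PM2.5_t + β2'·W_t + β3'·(PM2.5_t × W_t)
           + β4·Sex + β5'·Age + β6'·Job + β7'·DOW_t + β8·Smoking + S(t)
```

where `W_t` is either the vector of **eight non-exclusive extreme-weather
flags** (hot, cold, hyperbaria, hypobaria, humid, dry, windy, windless;
days beyond the pooled 10th/90th percentile of the relevant daily
statistic) or **five synoptic weather type (SWT) dummies** (hot dry, warm
humid, cold dry, moderate dry, moderate humid; cold humid as reference).
SWTs are built by standardizing 15 daily meteorological parameters,
retaining the principal components that explain ≥ 93 % of the variance
(six on the default synthetic data), K-means clustering the component
scores, and naming the six clusters from their temperature/humidity
centroids. `S(t)` is a cubic B-spline in calendar time with 5 interior
knots per year (15 for a three-year study).

Inference is fully Bayesian: Jeffreys' prior from the observed Fisher
information (or an informative normal prior for sensitivity analysis),
sampled by **adaptive rejection Metropolis sampling within Gibbs** with
3 chains, burn-in 1000, 5000 retained iterations thinned by 10.
Convergence is checked by Gelman–Rubin 97.5 % bounds (< 1.01), lag-5
autocorrelation (< 0.1), effective sample size (> 1000) and efficiency
(> 0.6); model fit by daily Pearson residuals (≈ 95 % within ±2).
Effects are reported as percent increase in mortality,
`100·(exp(10·β1) − 1)` per 10 µg/m³ PM2.5, with equal-tail 95 % credible
intervals from the pooled draws.

## Worked example

```r
library(pmgam)
study <- simulate_study("2012-01-01", "2013-12-31", seed = 42)
cfg <- sampler_config(n_chains = 3, burn_in = 500, n_iter = 2000, thin = 10,
                      seeds = 421:423)
fit <- fit_bgam(study, coding = "extreme", with_interaction = TRUE,
                prior = prior_spec("jeffreys"), config = cfg)
print(fit)
#> Bayesian Poisson GAM fit (extreme coding, with interaction)
#> 3 chains x 200 kept draws x 44 parameters
#> PM2.5 percent increase per 10 ug/m3: 0.32 (0.17, 0.49)

rep <- convergence_report(fit$chains, fit$design)
max(rep$gelman_rubin$upper)           # 1.0041  (< 1.01: converged)
rep$ess$table$ess[rep$ess$table$parameter == "pm25"]  # 600 pooled draws
100 * rep$residuals$fraction_within_2 # 95.2 % of daily residuals in ±2

combined_effect(0.27, 0.59)$exact     # 0.86 % per 10 ug/m3 on dry days
```

The generator's truth for this study is a PM2.5 effect of 0.30 % per
10 µg/m³, so the posterior `0.32 (0.17, 0.49)` recovers it: the interval
covers the truth and the diagnostics confirm the chains mixed. The
`combined_effect()` call shows how a main PM2.5 effect and a
PM2.5-by-weather interaction combine into the effect under that weather
condition (exact multiplicative rule; the additive shortcut agrees at
two decimals for effects below 2 %).

`run_pipeline()` chains every stage (simulate → features → fit →
diagnostics → effect tables) and writes CSV/JSON artifacts;
`write_study()` exports `meteorology.csv`, `pm25.csv`, `deaths.csv` and
`truth.json`. A thin command-line wrapper is provided in `inst/cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli.R", package="pmgam"))')" \
    simulate --start 2012-01-01 --end 2014-12-31 --seed 1 --out data/
```

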