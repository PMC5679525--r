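#' Default configuration of the 15 synthetic meteorological parameters
#'
#' The synoptic-typing pipeline expects 15 routinely monitored daily
#' parameters: three barometric pressure, three temperature, two
#' humidity, one precipitation, five wind-speed and one sunshine
#' parameter.  The generator uses a plausible station set: min/mean/max
#' for pressure and temperature, mean/min humidity, daily precipitation,
#' mean/min/max/gust/sd wind speed, and sunshine hours.
#'
#' Each parameter is driven by a shared annual sinusoid plus five latent
#' AR(1) weather factors (synoptic pressure, temperature anomaly, moisture,
#' wind, cloudiness) and a small idiosyncratic AR(1) term.  The loadings
#' are chosen so that the standardized 15-column matrix is approximately
#' rank six: the first six principal components carry >= 93% of the
#' variance while five do not, mirroring the dimensionality observed in
#' real synoptic station records.
#'
#' @return A data frame with one row per parameter: location/scale of the
#'   final series and loadings on the season and the five latent factors
#'   (`f1`..`f5`), plus the idiosyncratic standard deviation `idio`.
#' @export
default_met_params <- function() {
  p <- read.csv(text = "
name,group,center,scale,season,f1,f2,f3,f4,f5,idio
pressure_min,pressure,101.25,0.80,-0.52,0.76,-0.15,0,0,0,0.336
pressure_mean,pressure,101.60,0.85,-0.52,0.78,-0.15,0,0,0,0.308
pressure_max,pressure,101.95,0.90,-0.52,0.76,-0.15,0,0,0,0.336
temp_min,temperature,13.2,8.3,0.80,-0.12,0.50,0.08,0,0,0.308
temp_mean,temperature,17.2,8.6,0.81,-0.12,0.51,0.05,0,0,0.28
temp_max,temperature,21.6,9.0,0.80,-0.12,0.50,0,0,0.08,0.322
humidity_mean,humidity,70.3,12.0,0.18,-0.10,0.12,0.88,0,-0.18,0.392
humidity_min,humidity,52.0,14.0,0.18,-0.10,0.12,0.86,0,-0.20,0.434
precipitation,precipitation,0,1,0.10,-0.08,0,0.62,0.12,-0.35,0.77
wind_mean,wind,2.80,0.95,-0.05,0.14,0,0,0.88,0,0.42
wind_min,wind,1.10,0.60,-0.05,0.12,0,0,0.80,0,0.602
wind_max,wind,5.10,1.60,-0.05,0.14,0,0,0.87,0,0.448
wind_gust,wind,8.20,2.40,-0.05,0.13,0,0,0.84,0,0.532
wind_sd,wind,1.05,0.35,-0.05,0.12,0,0,0.78,0,0.63
sunshine,sunshine,4.70,3.90,0.25,0.10,0.10,-0.42,0,0.72,0.504
", stringsAsFactors = FALSE)
  p
}

# Unit-variance stationary AR(1) series of length n (marginal N(0, 1)).
ar1_series <- function(n, rho) {
  z <- numeric(n)
  z[1L] <- rnorm(1L)
  if (n > 1L) {
    innov <- rnorm(n - 1L) * sqrt(1 - rho^2)
    for (t in 2:n) z[t] <- rho * z[t - 1L] + innov[t - 1L]
  }
  z
}

#' Simulate daily meteorology with seasonal and low-rank synoptic structure
#'
#' Generates the 15-parameter daily meteorological matrix described in
#' [default_met_params()]: each standardized parameter is an annual
#' sinusoid plus a loading-weighted combination of five latent AR(1)
#' factors and idiosyncratic AR(1) noise, then mapped to physical units.
#' Min/mean/max triplets are built as mean plus strictly signed gaps so
#' their ordering always holds; humidity is clipped to \[0, 100\] and
#' precipitation, sunshine and wind speeds to nonnegative values.
#'
#' @param calendar Data frame from [generate_calendar()].
#' @param seasonal_params Optional numeric vector of length 15 that scales
#'   each parameter's seasonal amplitude (1 = default climate; 0 removes
#'   the annual cycle).
#' @param noise_params Optional list with elements `sd` (global multiplier
#'   on all stochastic terms, >= 0), `rho_factor` and `rho_idio`
#'   (autocorrelations of the latent factors and idiosyncratic terms).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @return A list of class `met_matrix` with `dates`, `values` (days x 15
#'   numeric matrix) and `parameter_names`.
#' @export
simulate_meteorology <- function(calendar, seasonal_params = NULL,
                                 noise_params = NULL, seed = 1L) {
  stopifnot(is.data.frame(calendar), nrow(calendar) >= 1L)
  pars <- default_met_params()
  if (is.null(seasonal_params)) seasonal_params <- rep(1, nrow(pars))
  if (length(seasonal_params) != nrow(pars)) {
    stop("seasonal_params must have length ", nrow(pars))
  }
  noise <- list(sd = 1, rho_factor = 0.78, rho_idio = 0.35)
  noise[names(noise_params)] <- noise_params
  if (noise$sd < 0) stop("noise sd must be nonnegative (AR variance >= 0)")

  n <- nrow(calendar)
  # Annual cycle peaking mid-July (day-of-year 196), as in a subtropical
  # northern-hemisphere coastal climate.
  season <- cos(2 * pi * (calendar$doy - 196) / 365.25)

  local_seed(seed, {
    nf <- 5L
    fac <- vapply(seq_len(nf), function(k) ar1_series(n, noise$rho_factor),
                  numeric(n))
    idio <- vapply(seq_len(nrow(pars)), function(j) ar1_series(n, noise$rho_idio),
                   numeric(n))
    lat <- matrix(0, n, nrow(pars))
    for (j in seq_len(nrow(pars))) {
      load <- as.numeric(pars[j, c("f1", "f2", "f3", "f4", "f5")])
      lat[, j] <- pars$season[j] * seasonal_params[j] * season +
        noise$sd * (fac %*% load + pars$idio[j] * idio[, j])
    }
    colnames(lat) <- pars$name
    g <- function(x) stats::pnorm(x)  # smooth positive gap driver

    v <- matrix(NA_real_, n, nrow(pars), dimnames = list(NULL, pars$name))
    # pressure triplet (kPa): mean, then ordered min/max via positive gaps
    v[, "pressure_mean"] <- 101.6 + 0.85 * lat[, "pressure_mean"]
    v[, "pressure_min"] <- v[, "pressure_mean"] - (0.20 + 0.45 * g(lat[, "pressure_min"]))
    v[, "pressure_max"] <- v[, "pressure_mean"] + (0.20 + 0.45 * g(lat[, "pressure_max"]))
    # temperature triplet (degrees C)
    v[, "temp_mean"] <- 17.2 + 8.6 * lat[, "temp_mean"]
    v[, "temp_min"] <- v[, "temp_mean"] - (2.2 + 4.0 * g(lat[, "temp_min"]))
    v[, "temp_max"] <- v[, "temp_mean"] + (2.0 + 4.6 * g(lat[, "temp_max"]))
    # humidity (%), clipped to [0, 100]
    v[, "humidity_mean"] <- pmin(100, pmax(0, 70.3 + 12 * lat[, "humidity_mean"]))
    v[, "humidity_min"] <- pmax(0, v[, "humidity_mean"] - (6 + 16 * g(lat[, "humidity_min"])))
    # precipitation (mm): thresholded latent gives realistic dry-day mass
    v[, "precipitation"] <- pmax(0, lat[, "precipitation"] - 0.55) * 11
    # wind speeds (m/s), nonnegative and ordered min <= mean <= max <= gust
    v[, "wind_mean"] <- pmax(0.2, 2.8 + 0.95 * lat[, "wind_mean"])
    v[, "wind_min"] <- pmax(0, v[, "wind_mean"] - (0.9 + 1.2 * g(lat[, "wind_min"])))
    v[, "wind_max"] <- v[, "wind_mean"] + (1.4 + 1.6 * g(lat[, "wind_max"]))
    v[, "wind_gust"] <- v[, "wind_max"] + (1.6 + 2.4 * g(lat[, "wind_gust"]))
    v[, "wind_sd"] <- pmax(0.02, 1.05 + 0.35 * lat[, "wind_sd"])
    # sunshine hours, clipped to a physical day length
    v[, "sunshine"] <- pmin(13.2, pmax(0, 4.7 + 3.9 * lat[, "sunshine"]))

    structure(list(dates = calendar$date, values = v,
                   parameter_names = pars$name),
              class = "met_matrix")
  })
}

#' Simulate daily PM2.5 coupled to temperature
#'
#' Daily mean PM2.5 (ug/m3) is log-normal with a log-scale mean driven by
#' the (standardized) daily mean temperature through a negative coupling,
#' so that concentrations are highest in the cold season, plus AR(1)
#' log-scale noise.  A fixed number of days is flagged missing,
#' preferentially in the first study year, emulating the early-record gaps
#' typical of newly deployed monitors.
#'
#' @param met A `met_matrix` from [simulate_meteorology()].
#' @param coupling Log-scale loading on standardized mean temperature;
#'   must be <= 0 (cold-season concentrations exceed warm-season ones).
#' @param seed Integer seed.
#' @param n_missing Number of days flagged missing (default 5).
#' @param mu0 Log-scale location (default `log(45)` ug/m3).
#' @param noise_sd,noise_rho AR(1) log-scale noise parameters.
#' @return Data frame of class `pm_series` with columns `date`, `pm25`
#'   (`NA` where missing) and logical `missing`.
#' @export
simulate_pm25 <- function(met, coupling = -0.50, seed = 1L, n_missing = 5L,
                          mu0 = log(45), noise_sd = 0.45, noise_rho = 0.55) {
  stopifnot(inherits(met, "met_matrix"))
  if (coupling > 0) {
    stop("coupling must be nonpositive: PM2.5 rises as temperature falls")
  }
  if (n_missing < 0) stop("n_missing must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  temp <- met$values[, "temp_mean"]
  tstd <- if (sd(temp) > 0) (temp - mean(temp)) / sd(temp) else temp * 0
  n <- length(temp)
  local_seed(seed, {
    eps <- if (noise_sd > 0) noise_sd * ar1_series(n, noise_rho) else numeric(n)
    pm <- exp(mu0 + coupling * tstd + eps)
    miss <- rep(FALSE, n)
    if (n_missing > 0) {
      yr <- as.integer(format(met$dates, "%Y"))
      pool <- which(yr == yr[1L])
      if (length(pool) < n_missing) pool <- seq_len(n)
      miss[sample(pool, n_missing)] <- TRUE
    }
    pm[miss] <- NA_real_
    structure(data.frame(date = met$dates, pm25 = pm, missing = miss),
              class = c("pm_series", "data.frame"))
  })
}

#' Default population strata for the synthetic registry
#'
#' The death-count generator works on day-by-stratum cells defined by sex,
#' age group and occupation.  The default keeps the strata compact (2
#' sexes x 4 age groups x 3 occupations = 24 cells) so that desk-scale
#' fits remain fast; `full = TRUE` switches to the full 11-occupation
#' coding.  Smoking rate (%) is assigned per sex-age cell: the sex-level
#' values reproduce typical standardized urban-China rates (about 29.7%
#' for men, 0.9% for women) with a plausible age gradient, which also
#' keeps the smoking covariate linearly independent of the sex and age
#' dummies.
#'
#' @param full Logical; use all 11 occupation categories.
#' @return A data frame with one row per stratum: `sex`, `age_group`,
#'   `occupation`, `smoking_rate`.
#' @export
default_strata <- function(full = FALSE) {
  sexes <- c("Male", "Female")
  ages <- c("0-14", "15-39", "40-64", "65+")
  occs <- if (full) {
    c("Manufactory", "Governmental", "Professional", "Administrative",
      "Business", "Agriculture", "Military", "Others", "Preschool",
      "Students", "Jobless")
  } else {
    c("Manufactory", "Agriculture", "Professional")
  }
  g <- expand.grid(sex = sexes, age_group = ages, occupation = occs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  smoke <- matrix(c(0.5, 24, 34, 29.71,   # male by age group
                    0.0, 0.5, 1.0, 0.95), # female by age group
                  nrow = 2, byrow = TRUE,
                  dimnames = list(sexes, ages))
  g$smoking_rate <- smoke[cbind(g$sex, g$age_group)]
  g$sex <- factor(g$sex, levels = sexes)
  g$age_group <- factor(g$age_group, levels = ages)
  g$occupation <- factor(g$occupation, levels = occs)
  g
}

#' Default coefficient truth for the synthetic study
#'
#' Ground-truth regression coefficients for the death-count generator, on
#' the log-rate scale of the Poisson model.  Magnitudes are chosen to
#' resemble a large-city mortality registry: a PM2.5 effect of about 0.3%
#' per 10 ug/m3, weather-condition effects of a few percent, strong
#' age/occupation contrasts, a female excess conditional on smoking, and
#' a smoking slope of about 2% per percentage point.  The intercept is
#' calibrated so the default strata produce roughly 300 deaths per day.
#'
#' @param coding `"extreme"` (8 non-exclusive extreme-weather flags) or
#'   `"swt"` (5 synoptic-weather-type dummies, cold humid as reference).
#' @param full_occupation Logical; truth vector for the 11-occupation coding.
#' @param pm25_pct_per10 True percent increase per 10 ug/m3 PM2.5.
#' @return A list of class `coefficient_truth`; see the field names.
#' @export
default_truth <- function(coding = c("extreme", "swt"),
                          full_occupation = FALSE,
                          pm25_pct_per10 = 0.30) {
  coding <- match.arg(coding)
  pct <- function(x) log(1 + x / 100)
  if (coding == "extreme") {
    weather <- pct(c(hot = 3.59, cold = 0.02, hyperbaria = 0.73,
                     hypobaria = -1.55, humid = 1.41, dry = -4.80,
                     windy = 3.75, windless = 0.54))
    inter <- pct(c(hot = 0.50, cold = 0.12, hyperbaria = -0.02,
                   hypobaria = 0.62, humid = -0.12, dry = 0.59,
                   windy = -0.22, windless = -0.15)) / 10
  } else {
    weather <- pct(c(`hot dry` = 1.51, `warm humid` = -0.32,
                     `cold dry` = -1.84, `moderate dry` = 2.78,
                     `moderate humid` = 4.37))
    inter <- pct(c(`hot dry` = 1.02, `warm humid` = 0.38, `cold dry` = 0.00,
                   `moderate dry` = -0.16, `moderate humid` = 0.16)) / 10
  }
  job <- if (full_occupation) {
    pct(c(Governmental = -97.78, Professional = -76.62,
          Administrative = -69.82, Business = -73.55, Agriculture = -37.25,
          Military = -99.84, Others = -97.43, Preschool = -99.15,
          Students = -99.73, Jobless = -77.63))
  } else {
    pct(c(Agriculture = -37.25, Professional = -76.62))
  }
  truth <- list(
    intercept = 3.79,
    pm25_slope = pct(pm25_pct_per10) / 10,
    weather_effects = weather,
    interaction_effects = inter,
    sex_effect = pct(47.6),
    age_effects = pct(c(`0-14` = -98.81, `15-39` = -99.32, `40-64` = -94.42)),
    job_effects = job,
    dow_effects = pct(c(Monday = 1.73, Tuesday = 0.70, Wednesday = 0.89,
                        Thursday = 0.07, Friday = 0.03, Saturday = 0.04)),
    smoking_slope = pct(2.01),
    trend_amplitude = 0.15,
    coding = coding
  )
  stopifnot(all(vapply(truth[1:10], function(x) all(is.finite(x)), TRUE)),
            truth$trend_amplitude >= 0)
  class(truth) <- "coefficient_truth"
  truth
}

#' Seasonal mortality trend used as the generator's smooth term
#'
#' The smooth time trend injected into the synthetic log rate: a winter
#' peaking annual cosine, `amplitude * cos(2 * pi * (doy - 15) / 365.25)`,
#' emulating the excess winter mortality that the B-spline smoother must
#' absorb during fitting.
#'
#' @param dates `Date` vector.
#' @param amplitude Nonnegative amplitude on the log-rate scale.
#' @return Numeric vector, one value per date.
#' @export
seasonal_trend <- function(dates, amplitude = 0.15) {
  stopifnot(amplitude >= 0)
  doy <- as.integer(format(as.Date(dates), "%j"))
  amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

# Day-level linear predictor contribution shared by the generator.
# features: data.frame with date, dow and either the 8 flag columns or swt.
day_eta_from_truth <- function(features, pm25, truth, spline_truth) {
  n <- nrow(features)
  w_names <- names(truth$weather_effects)
  if (truth$coding == "swt" || "swt" %in% names(features)) {
    if (!"swt" %in% names(features)) {
      stop("truth uses SWT coding but features has no 'swt' column")
    }
    W <- vapply(w_names, function(nm) as.numeric(features$swt == nm),
                numeric(n))
    unknown <- setdiff(levels(factor(features$swt)), c(w_names, "cold humid"))
    if (length(unknown)) {
      stop("SWT levels not covered by weather_effects: ",
           paste(unknown, collapse = ", "))
    }
  } else {
    missing_cols <- setdiff(w_names, names(features))
    if (length(missing_cols)) {
      stop("features lacks weather flag column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    W <- vapply(w_names, function(nm) as.numeric(features[[nm]]), numeric(n))
  }
  if (length(truth$interaction_effects) != length(truth$weather_effects)) {
    stop("interaction_effects length must match weather_effects")
  }
  dow_eff <- c(Sunday = 0, truth$dow_effects)[as.character(features$dow)]
  if (anyNA(dow_eff)) stop("dow_effects does not cover all day-of-week levels")
  st <- if (is.null(spline_truth)) {
    seasonal_trend(features$date, truth$trend_amplitude)
  } else if (is.function(spline_truth)) {
    spline_truth(features$date)
  } else {
    as.numeric(spline_truth)
  }
  drop(truth$pm25_slope * pm25 +
         W %*% truth$weather_effects +
         (pm25 * W) %*% truth$interaction_effects +
         dow_eff + st)
}

#' Simulate stratified daily death counts with known coefficient truth
#'
#' Draws Poisson death counts per day-by-stratum cell from the generative
#' log-linear model: the log rate is intercept + PM2.5 slope + weather
#' effects + PM2.5-by-weather interactions + sex/age/occupation dummies +
#' day-of-week effects + smoking-rate slope + a smooth seasonal trend.
#' Days with missing PM2.5 are dropped (complete-case) by default.
#'
#' @param features Data frame with `date`, `dow` and the weather coding
#'   matching `truth`: logical flag columns `hot`..`windless` for extreme
#'   coding, or a `swt` factor for synoptic-type coding.
#' @param pm A `pm_series` from [simulate_pm25()] (or a data frame with
#'   `date` and `pm25`).
#' @param truth A `coefficient_truth`, e.g. [default_truth()].
#' @param strata_spec Data frame of strata, e.g. [default_strata()].
#' @param spline_truth Optional smooth trend: a function of dates, a
#'   numeric vector (one value per feature row), or `NULL` for
#'   [seasonal_trend()] with `truth$trend_amplitude`.
#' @param seed Integer seed.
#' @param missing_pm `"drop"` (default) to exclude missing-PM2.5 days or
#'   `"error"` to refuse them.
#' @return Data frame of class `stratum_counts`: one row per date-stratum
#'   with `deaths` and the stratum covariates.  The per-row true log rate
#'   is attached as attribute `"eta"`.
#' @export
simulate_deaths <- function(features, pm, truth, strata_spec = default_strata(),
                            spline_truth = NULL, seed = 1L,
                            missing_pm = c("drop", "error")) {
  missing_pm <- match.arg(missing_pm)
  stopifnot(inherits(truth, "coefficient_truth"), is.data.frame(strata_spec))
  pm <- pm[match(features$date, pm$date), , drop = FALSE]
  if (anyNA(pm$pm25)) {
    if (missing_pm == "error") stop("missing PM2.5 on included days")
    keep <- !is.na(pm$pm25)
    features <- features[keep, , drop = FALSE]
    pm <- pm[keep, , drop = FALSE]
  }
  n_age <- nlevels(strata_spec$age_group) - 1L
  if (length(truth$age_effects) != n_age) {
    stop("age_effects length (", length(truth$age_effects),
         ") does not match non-reference age groups (", n_age, ")")
  }
  n_job <- nlevels(strata_spec$occupation) - 1L
  if (length(truth$job_effects) != n_job) {
    stop("job_effects length (", length(truth$job_effects),
         ") does not match non-reference occupations (", n_job, ")")
  }

  eta_day <- day_eta_from_truth(features, pm$pm25, truth, spline_truth)

  # reference age = 65+, reference occupation = first level (Manufactory)
  age_eff <- c(truth$age_effects, `65+` = 0)
  job_eff <- c(stats::setNames(0, levels(strata_spec$occupation)[1L]),
               truth$job_effects)
  eta_str <- truth$intercept +
    ifelse(strata_spec$sex == "Female", truth$sex_effect, 0) +
    age_eff[as.character(strata_spec$age_group)] +
    job_eff[as.character(strata_spec$occupation)] +
    truth$smoking_slope * strata_spec$smoking_rate
  if (anyNA(eta_str)) stop("strata levels not covered by truth effects")

  nd <- nrow(features)
  ns <- nrow(strata_spec)
  eta <- rep(eta_day, each = ns) + rep(eta_str, times = nd)
  out <- data.frame(
    date = rep(features$date, each = ns),
    strata_spec[rep(seq_len(ns), times = nd), , drop = FALSE],
    row.names = NULL
  )
  local_seed(seed, {
    out$deaths <- rpois(length(eta), exp(eta))
  })
  attr(out, "eta") <- eta
  class(out) <- c("stratum_counts", "data.frame")
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining the calendar, meteorology, PM2.5,
#' extreme-flag / synoptic-type features and stratified death counts, with
#' per-stage seeds derived deterministically from one master seed.
#'
#' @param start_date,end_date Study period (default three calendar years).
#' @param seed Master seed; stage seeds are `seed + 101/202/303`.
#' @param truth Coefficient truth (default [default_truth()]).
#' @param strata_spec Strata (default reduced [default_strata()]).
#' @param n_missing_pm Number of missing PM2.5 days.
#' @param swt Logical; also compute synoptic weather types (requires
#'   enough days for a stable clustering; skipped with a message if the
#'   clustering cannot retain components).
#' @return List with `calendar`, `met`, `pm`, `flags`, `features`,
#'   `counts`, `truth`, and `swt` labels when requested.
#' @export
simulate_study <- function(start_date = "2012-01-01", end_date = "2014-12-31",
                           seed = 1L, truth = default_truth(),
                           strata_spec = default_strata(),
                           n_missing_pm = 5L, swt = FALSE) {
  calendar <- generate_calendar(start_date, end_date)
  met <- simulate_meteorology(calendar, seed = seed + 101L)
  pm <- simulate_pm25(met, seed = seed + 202L, n_missing = n_missing_pm)
  flags <- compute_extreme_flags(met)
  features <- cbind(calendar, flags[, flag_names()])
  swt_labels <- NULL
  if (isTRUE(swt) || truth$coding == "swt") {
    swt_labels <- classify_swt(met, seed = seed + 404L)
    features$swt <- swt_labels$label
  }
  counts <- simulate_deaths(features, pm, truth, strata_spec,
                            seed = seed + 303L)
  list(calendar = calendar, met = met, pm = pm, flags = flags,
       features = features, counts = counts, truth = truth,
       strata = strata_spec, swt = swt_labels)
}

#' Write a simulated study to delimited text files
#'
#' Writes `meteorology.csv`, `pm25.csv` and `deaths.csv` (RFC-4180 CSV)
#' plus `truth.json` recording the generating coefficients.
#'
#' @param study A list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- data.frame(date = study$met$dates, study$met$values)
  write.csv(met, file.path(dir, "meteorology.csv"), row.names = FALSE)
  write.csv(study$pm, file.path(dir, "pm25.csv"), row.names = FALSE)
  write.csv(study$counts, file.path(dir, "deaths.csv"), row.names = FALSE)
  tr <- study$truth
  tr$coding <- as.character(tr$coding)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
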