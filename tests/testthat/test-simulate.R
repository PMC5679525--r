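test_that("calendar spans inclusive ranges with correct day counts", {
  expect_equal(nrow(generate_calendar("2012-01-01", "2014-12-31")), 1096L)
  expect_equal(nrow(generate_calendar("2012-01-01", "2012-01-01")), 1L)
  # brute-force enumeration oracle for a leap year
  oracle <- length(seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day"))
  expect_equal(nrow(generate_calendar("2012-01-01", "2012-12-31")), oracle)
  expect_equal(oracle, 366L)
  expect_error(generate_calendar("2014-01-01", "2012-01-01"), "after")
})

test_that("calendar day-of-week follows the proleptic Gregorian calendar", {
  cal <- generate_calendar("2012-01-01", "2012-01-14")
  expect_equal(as.character(cal$dow[1]), "Sunday")  # 2012-01-01 was a Sunday
  expect_equal(as.character(cal$dow[3]), "Tuesday")
  expect_true(all(table(cal$dow) == 2))
})

test_that("meteorology is deterministic, ordered, and physically bounded", {
  cal <- generate_calendar("2012-01-01", "2012-03-31")
  m1 <- simulate_meteorology(cal, seed = 9)
  m2 <- simulate_meteorology(cal, seed = 9)
  expect_identical(m1$values, m2$values)
  v <- m1$values
  expect_false(anyNA(v))
  expect_true(all(v[, "temp_min"] <= v[, "temp_mean"] &
                    v[, "temp_mean"] <= v[, "temp_max"]))
  expect_true(all(v[, "pressure_min"] <= v[, "pressure_mean"] &
                    v[, "pressure_mean"] <= v[, "pressure_max"]))
  expect_true(all(v[, "humidity_mean"] >= 0 & v[, "humidity_mean"] <= 100))
  expect_true(all(v[, c("precipitation", "sunshine", "wind_mean",
                        "wind_min", "wind_max", "wind_gust")] >= 0))
  expect_true(all(v[, "wind_mean"] <= v[, "wind_max"]))
})

test_that("degenerate generator settings give a constant matrix; negative noise errors", {
  cal <- generate_calendar("2012-01-01", "2012-02-29")
  m <- simulate_meteorology(cal, seasonal_params = rep(0, 15),
                            noise_params = list(sd = 0), seed = 1)
  expect_true(all(apply(m$values, 2, sd) == 0))
  expect_error(simulate_meteorology(cal, noise_params = list(sd = -1)),
               "nonnegative")
})

test_that("default meteorology needs exactly six standardized PCs for 93% variance", {
  cal <- generate_calendar("2012-01-01", "2014-12-31")
  met <- simulate_meteorology(cal, seed = 1)
  pc <- standardize_and_pca(met)
  expect_equal(pc$k, 6L)
  expect_gte(pc$cumulative[6], 0.93)
  expect_lt(pc$cumulative[5], 0.93)
})

test_that("PM2.5 shows the cold-season excess, exact missingness, and determinism", {
  cal <- generate_calendar("2012-01-01", "2014-12-31")
  met <- simulate_meteorology(cal, seed = 1)
  pm <- simulate_pm25(met, seed = 1, n_missing = 5)
  expect_equal(sum(pm$missing), 5L)
  expect_equal(sum(is.na(pm$pm25)), 5L)
  mo <- format(pm$date, "%m")
  expect_gt(mean(pm$pm25[mo == "12"], na.rm = TRUE),
            mean(pm$pm25[mo == "08"], na.rm = TRUE))
  expect_true(all(pm$pm25 >= 0, na.rm = TRUE))
  expect_identical(pm, simulate_pm25(met, seed = 1, n_missing = 5))
  expect_error(simulate_pm25(met, n_missing = -1), "nonnegative")
  expect_error(simulate_pm25(met, coupling = 0.2), "nonpositive")
})

test_that("zero coupling and zero noise give a constant PM2.5 series", {
  cal <- generate_calendar("2012-01-01", "2012-03-31")
  met <- simulate_meteorology(cal, seed = 2)
  pm <- simulate_pm25(met, coupling = 0, noise_sd = 0, seed = 1, n_missing = 0)
  expect_equal(unique(pm$pm25), 45)
})

test_that("death counts recover the intended daily mean for a null model", {
  # all slopes zero, one stratum, intercept log(307): daily mean ~ 307
  cal <- generate_calendar("2012-01-01", "2014-12-31")
  met <- simulate_meteorology(cal, seed = 1)
  pm <- simulate_pm25(met, seed = 1, n_missing = 0)
  flags <- compute_extreme_flags(met)
  features <- cbind(cal, flags[, flag_names()])
  truth <- default_truth()
  truth$intercept <- log(307)
  truth$pm25_slope <- 0
  truth$weather_effects[] <- 0
  truth$interaction_effects[] <- 0
  truth$sex_effect <- 0
  truth$age_effects <- truth$age_effects[0]
  truth$job_effects <- truth$job_effects[0]
  truth$dow_effects[] <- 0
  truth$smoking_slope <- 0
  truth$trend_amplitude <- 0
  strata <- data.frame(sex = factor("Male"), age_group = factor("65+"),
                       occupation = factor("Manufactory"), smoking_rate = 0)
  counts <- simulate_deaths(features, pm, truth, strata, seed = 5)
  se <- sqrt(307 / nrow(counts))
  expect_lt(abs(mean(counts$deaths) - 307), 3 * se)
})

test_that("simulated counts match the closed-form Poisson mean on replicate days", {
  # 10,000 replicate days at a known eta; oracle: analytic Poisson mean
  cal <- generate_calendar("2012-01-01", "2012-01-01")
  features <- cal[rep(1, 10000), ]
  features$date <- features$date + seq_len(10000) - 1
  features$dow <- factor("Sunday", levels = levels(cal$dow))
  for (f in flag_names()) features[[f]] <- FALSE
  pm <- data.frame(date = features$date, pm25 = 50, missing = FALSE)
  truth <- default_truth()
  truth$age_effects <- truth$age_effects[0]
  truth$job_effects <- truth$job_effects[0]
  truth$trend_amplitude <- 0
  strata <- data.frame(sex = factor("Male"), age_group = factor("65+"),
                       occupation = factor("Manufactory"), smoking_rate = 10)
  counts <- simulate_deaths(features, pm, truth, strata, seed = 7,
                            spline_truth = rep(0, nrow(features)))
  eta <- truth$intercept + truth$pm25_slope * 50 + truth$smoking_slope * 10
  mu <- exp(eta)
  expect_lt(abs(mean(counts$deaths) - mu), 4 * sqrt(mu / 10000))
  # Poisson mean-variance property (index of dispersion near 1)
  disp <- var(counts$deaths) / mean(counts$deaths)
  expect_lt(abs(disp - 1), 4 * sqrt(2 / 10000))
})

test_that("count tables conserve the calendar: one row per date and stratum", {
  st <- tiny_study()
  n_days_used <- length(unique(st$counts$date))
  expect_equal(nrow(st$counts), n_days_used * nrow(st$strata))
  tab <- table(st$counts$date)
  expect_true(all(tab == nrow(st$strata)))
  # complete-case: exactly the non-missing PM days survive
  expect_equal(sort(unique(st$counts$date)),
               st$pm$date[!is.na(st$pm$pm25)])
})

test_that("rate underflow and mismatched truth vectors are handled", {
  st <- tiny_study()
  truth <- st$truth
  truth$intercept <- -Inf
  counts <- simulate_deaths(st$features, st$pm, truth, st$strata, seed = 1)
  expect_true(all(counts$deaths == 0))
  bad <- st$truth
  bad$interaction_effects <- bad$interaction_effects[-1]
  expect_error(simulate_deaths(st$features, st$pm, bad, st$strata),
               "interaction_effects")
  bad2 <- st$truth
  bad2$age_effects <- bad2$age_effects[-1]
  expect_error(simulate_deaths(st$features, st$pm, bad2, st$strata),
               "age_effects")
})

test_that("study files are written as plain CSV plus truth JSON", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c("meteorology.csv", "pm25.csv",
                                               "deaths.csv", "truth.json")))))
  rt <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(rt$pm25_slope, st$truth$pm25_slope)
  met_in <- read.csv(file.path(dir, "meteorology.csv"))
  expect_equal(nrow(met_in), length(st$met$dates))
})
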