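mk_chains <- function(..., names = NULL) {
  chs <- list(...)
  n <- length(chs[[1]])
  a <- array(NA_real_, dim = c(length(chs), n, 1),
             dimnames = list(NULL, NULL, names %||% "b"))
  for (i in seq_along(chs)) a[i, , 1] <- chs[[i]]
  a
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PSRF is near one for chains from a common target", {
  set.seed(71)
  a <- mk_chains(rnorm(5000), rnorm(5000), rnorm(5000))
  gr <- gelman_rubin(a)
  expect_gte(gr$psrf, 1 - 1e-3)
  expect_lt(gr$upper, 1.01)
  expect_true(gr$pass)
})

test_that("PSRF matches the hand-computed B/W formula for separated chains", {
  set.seed(72)
  n <- 400
  x1 <- rnorm(n, 0, 1)
  x2 <- rnorm(n, 10, 1)
  gr <- gelman_rubin(mk_chains(x1, x2))
  expect_gt(gr$psrf, 5)
  # direct hand evaluation of the estimator: between/within decomposition
  # plus the degrees-of-freedom adjustment
  m <- 2
  s2 <- c(var(x1), var(x2))
  xbar <- c(mean(x1), mean(x2))
  W <- mean(s2)
  B <- n * var(xbar)
  V <- (n - 1) / n * W + (1 + 1 / m) * B / n
  var_V <- ((n - 1)^2 * var(s2) / m + (1 + 1 / m)^2 * 2 * B^2 / (m - 1) +
              2 * (n - 1) * (1 + 1 / m) * (n / m) *
                (cov(s2, xbar^2) - 2 * mean(c(x1, x2)) * cov(s2, xbar))) / n^2
  df_V <- 2 * V^2 / var_V
  expect_equal(gr$psrf, sqrt((df_V + 3) / (df_V + 1) * V / W),
               tolerance = 1e-8)
  expect_gte(gr$upper, gr$psrf)
})

test_that("PSRF decreases toward 1 with chain length and needs >= 2 chains", {
  set.seed(73)
  short <- gelman_rubin(mk_chains(rnorm(100), rnorm(100)))
  long <- gelman_rubin(mk_chains(rnorm(10000), rnorm(10000)))
  expect_lt(long$psrf, short$psrf + 0.02)
  expect_lt(abs(long$psrf - 1), 0.005)
  expect_error(gelman_rubin(array(rnorm(100), c(1, 100, 1))), "2 chains")
})

test_that("independent draws give near-zero lag-1 ACF and ESS near N", {
  set.seed(74)
  er <- ess_autocorr(mk_chains(rnorm(2000), rnorm(2000)))
  expect_lt(abs(er$acf[1, 1]), 0.06)
  expect_gt(er$table$ess, 4000 * 0.85)
  expect_lte(er$table$ess, 4000)
  expect_gt(er$table$efficiency, 0.85)
})

test_that("ESS of an AR(1) chain matches its closed form within 10%", {
  rho <- 0.5
  gen <- function(n, seed) {
    set.seed(seed)
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1, sd = sqrt(1 - rho^2))
    x
  }
  er <- ess_autocorr(mk_chains(gen(20000, 1), gen(20000, 2)))
  # oracle: ESS/N = (1 - rho) / (1 + rho) = 1/3
  expect_lt(abs(er$table$efficiency - 1 / 3), 0.1 / 3)
})

test_that("ESS on independent draws stays within 15% of N across seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    er <- ess_autocorr(mk_chains(rnorm(2000), rnorm(2000)))
    abs(er$table$ess - 4000) / 4000
  }, 0)
  expect_lt(max(errs), 0.15)
})

test_that("constant chains are flagged rather than crashing ESS", {
  er <- ess_autocorr(mk_chains(rep(2, 500), rep(2, 500)))
  expect_true(er$table$constant)
  expect_true(is.na(er$table$ess))
})

test_that("Pearson residuals are zero at a perfect fit and ~95% within 2", {
  set.seed(75)
  n <- 1000
  mu <- 300
  y <- rpois(n, mu)
  d <- intercept_design(y)
  # exact fit: residual 0 when Y equals the fitted value
  r0 <- standardized_residuals(intercept_design(rep(300L, 10)), log(300))
  expect_lt(max(abs(r0$residuals)), 1e-10)
  expect_equal(r0$fraction_within_2, 1)
  # well-specified fit at large mu: normal approximation gives ~95%
  r <- standardized_residuals(d, log(mu))
  expect_gt(r$fraction_within_2, 0.93)
  rep <- standardized_residuals(d, fit_posterior_mode(d)$beta)
  expect_gt(rep$fraction_within_2, 0.93)
})

test_that("zero fitted rates with observed deaths are flagged", {
  d <- intercept_design(c(3L, 0L))
  r <- standardized_residuals(d, -800)  # exp underflows to 0
  expect_equal(r$flagged, 1L)
})
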