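test_that("intercept-only posterior matches the closed-form Gamma law", {
  set.seed(4)
  y <- rpois(60, 5)
  d <- intercept_design(y)
  cfg <- sampler_config(n_chains = 2, burn_in = 200, n_iter = 5000, thin = 1,
                        seeds = c(5, 6))
  ch <- run_chains(d, prior_spec("flat"), cfg)
  lam <- exp(pooled_draws(ch)[, 1])
  # flat prior on beta = log(lambda): p(lambda) ~ Gamma(sum(y), rate n)
  grid <- sort(lam)
  sup <- max(abs(ecdf(lam)(grid) - pgamma(grid, shape = sum(y), rate = 60)))
  expect_lt(sup, 0.02)
})

test_that("sampler configuration validates its run lengths", {
  expect_error(sampler_config(n_iter = 0), "positive")
  expect_error(sampler_config(burn_in = 0), "positive")
  expect_error(sampler_config(n_iter = 5000, thin = 7), "multiple")
  cfg <- sampler_config()
  expect_equal(cfg$n_iter %/% cfg$thin, 500L)  # kept draws per chain
  expect_equal(cfg$n_chains, 3L)
})

test_that("chains are reproducible and respect kept-draw counts", {
  set.seed(14)
  y <- rpois(40, 8)
  d <- intercept_design(y)
  cfg <- sampler_config(n_chains = 2, burn_in = 100, n_iter = 400, thin = 4,
                        seeds = c(1, 2))
  a <- run_chains(d, prior_spec("flat"), cfg)
  b <- run_chains(d, prior_spec("flat"), cfg)
  expect_identical(a$draws, b$draws)
  expect_equal(dim(a$draws), c(2L, 100L, 1L))
  expect_true(all(is.finite(a$draws)))
})

test_that("posterior summaries behave on constants, normals and transforms", {
  const <- array(2.5, dim = c(1, 200, 1), dimnames = list(NULL, NULL, "c"))
  s <- posterior_summary(const)
  expect_equal(s$mean, 2.5)
  expect_equal(c(s$lower, s$upper), c(2.5, 2.5))
  set.seed(15)
  z <- array(rnorm(100000), dim = c(1, 100000, 1),
             dimnames = list(NULL, NULL, "z"))
  sz <- posterior_summary(z)
  expect_lt(abs(sz$lower - (-1.96)), 0.02)
  expect_lt(abs(sz$upper - 1.96), 0.02)
  # equal-tail interval commutes with monotone transforms (up to the
  # interpolation step of the empirical quantile)
  se <- posterior_summary(exp(z[1, , 1, drop = FALSE]))
  sz2 <- posterior_summary(z)
  expect_lt(abs(se$lower - exp(sz2$lower)), 1e-5)
  expect_lt(abs(se$upper - exp(sz2$upper)), 1e-5)
  expect_error(posterior_summary(matrix(numeric(0), 0, 1)), "no draws")
})

test_that("permuting design columns permutes posterior summaries", {
  set.seed(16)
  n <- 150
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, a = x, b = as.numeric(x > 0.5))
  y <- rpois(n, exp(1 + 0.3 * X[, "a"] + 0.2 * X[, "b"]))
  mk <- function(Xm) structure(list(X = Xm, y = y, day = seq_len(n),
                                    dates = as.Date("2012-01-01") + seq_len(n),
                                    blocks = list(), n_days = n),
                               class = "bgam_design")
  cfg <- sampler_config(n_chains = 2, burn_in = 200, n_iter = 2000, thin = 2,
                        seeds = c(3, 4))
  s1 <- posterior_summary(run_chains(mk(X), prior_spec("flat"), cfg))
  s2 <- posterior_summary(run_chains(mk(X[, c(1, 3, 2)]), prior_spec("flat"), cfg))
  for (p in c("a", "b")) {
    i1 <- match(p, s1$parameter)
    i2 <- match(p, s2$parameter)
    expect_lt(abs(s1$mean[i1] - s2$mean[i2]),
              4 * (s1$sd[i1] / sqrt(200)) + 0.01)
  }
})

test_that("zero-iteration configurations are rejected by the sampler core", {
  d <- intercept_design(rpois(10, 2))
  expect_error(
    run_chains(d, prior_spec("flat"),
               structure(list(n_chains = 1L, burn_in = 10L, n_iter = 0L,
                              thin = 1L, seeds = 1L, bound = 50,
                              init_jitter = 1), class = "sampler_config")),
    "positive")
})

test_that("linearized Jeffreys sampling matches the exact-prior posterior", {
  # small model where the exact Jeffreys posterior is available by
  # numerical integration on a grid
  set.seed(17)
  y <- rpois(25, 4)
  d <- intercept_design(y)
  cfg <- sampler_config(n_chains = 2, burn_in = 200, n_iter = 4000, thin = 2,
                        seeds = c(7, 8))
  ch <- run_chains(d, prior_spec("jeffreys", refresh = 1), cfg)
  draws <- pooled_draws(ch)[, 1]
  grid <- seq(min(draws) - 0.3, max(draws) + 0.3, length.out = 4001)
  logp <- vapply(grid, function(b) log_likelihood(b, d) +
                   log_prior_jeffreys(b, d), 0)
  w <- exp(logp - max(logp))
  cdf <- cumsum(w) / sum(w)
  grid_cdf <- stats::approxfun(grid, cdf, rule = 2)
  sup <- max(abs(ecdf(draws)(sort(draws)) - grid_cdf(sort(draws))))
  expect_lt(sup, 0.025)
})
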