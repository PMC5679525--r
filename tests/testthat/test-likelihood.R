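test_that("Poisson log-likelihood matches closed forms and the dpois oracle", {
  d <- intercept_design(0L)
  expect_equal(log_likelihood(0, d), -1)  # Y = 0, eta = 0 -> -mu = -1
  set.seed(61)
  y <- rpois(5, 3)
  d5 <- intercept_design(y)
  beta <- 0.7
  oracle <- log(prod(dpois(y, exp(beta))))  # brute-force product of pmfs
  expect_equal(log_likelihood(beta, d5), oracle, tolerance = 1e-12)
  expect_equal(log_likelihood(beta, d5),
               sum(dpois(y, exp(beta), log = TRUE)), tolerance = 1e-12)
  expect_error(log_likelihood(0, d5, y = c(1.5, 1, 1, 1, 1)), "integers")
  # finite eta never returns -Inf
  expect_true(is.finite(log_likelihood(600, d5)))
})

test_that("Jeffreys prior matches its closed form for an intercept model", {
  n <- 23
  d <- intercept_design(rpois(n, 2))
  beta <- 0.4
  # I(beta) = n * exp(beta) so the log prior is (log n + beta) / 2
  expect_equal(log_prior_jeffreys(beta, d), 0.5 * (log(n) + beta),
               tolerance = 1e-12)
  expect_error(log_prior_jeffreys(1e6, d), "non-finite")
})

test_that("Jeffreys prior matches a finite-difference observed-information oracle", {
  set.seed(62)
  n <- 40
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  y <- rpois(n, exp(0.5 + 0.3 * X[, 2]))
  d <- structure(list(X = X, y = y, day = seq_len(n),
                      dates = as.Date("2012-01-01") + seq_len(n),
                      blocks = list(), n_days = n), class = "bgam_design")
  beta <- c(0.4, 0.2)
  # oracle: numerically differentiated Hessian of the log-likelihood
  eps <- 1e-5
  hess <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    bpp <- bpm <- bmp <- bmm <- beta
    bpp[i] <- bpp[i] + eps; bpp[j] <- bpp[j] + eps
    bpm[i] <- bpm[i] + eps; bpm[j] <- bpm[j] - eps
    bmp[i] <- bmp[i] - eps; bmp[j] <- bmp[j] + eps
    bmm[i] <- bmm[i] - eps; bmm[j] <- bmm[j] - eps
    hess[i, j] <- (log_likelihood(bpp, d) - log_likelihood(bpm, d) -
                     log_likelihood(bmp, d) + log_likelihood(bmm, d)) / (4 * eps^2)
  }
  oracle <- 0.5 * as.numeric(determinant(-hess)$modulus)
  expect_equal(log_prior_jeffreys(beta, d), oracle, tolerance = 1e-4)
})

test_that("Jeffreys prior is locally flat where the likelihood concentrates", {
  set.seed(63)
  n <- 500
  d <- intercept_design(rpois(n, 5))
  mode <- fit_posterior_mode(d)$beta
  se <- fit_posterior_mode(d)$se
  # prior varies by ~se/2 over a 1-SE move; likelihood varies by ~0.5
  dp <- abs(log_prior_jeffreys(mode + se, d) - log_prior_jeffreys(mode, d))
  dl <- abs(log_likelihood(mode + se, d) - log_likelihood(mode, d))
  expect_lt(dp, 0.1 * dl + 0.05)
})

test_that("normal prior obeys the Gaussian identities and flags bad sds", {
  beta <- c(0.3, -0.2, 1)
  m <- c(0.3, -0.2, 1)
  s <- c(1, 2, 0.5)
  at_mean <- log_prior_normal(beta, m, s)
  expect_equal(log_prior_normal(beta + s, m, s), at_mean - 1.5)  # 0.5 per coord
  expect_gt(at_mean, log_prior_normal(beta + 0.1, m, s))
  expect_error(log_prior_normal(beta, m, c(1, -1, 1)), "positive")
  # coefficients with infinite sd stay flat
  expect_equal(log_prior_normal(c(5, 0), c(0, 0), c(Inf, 1)),
               dnorm(0, log = TRUE))
})

test_that("an informative prior mean converts from a published percent increase", {
  # a reported 0.22% increase per 10 ug/m3 implies this slope per ug/m3
  expect_equal(log(1.0022) / 10, 0.00021976, tolerance = 1e-4)
  expect_equal(percent_increase(log(1.0022) / 10)$estimate, 0.22,
               tolerance = 1e-10)
  p <- prior_spec("normal", mean = log(1.0022) / 10, sd = 1e-4)
  expect_equal(p$mean, log(1.0022) / 10)
})

test_that("flat-prior posterior mode equals the IRLS Poisson fit", {
  st <- tiny_study()
  d <- build_design_matrix(st$counts, st$pm, st$flags, with_interaction = TRUE)
  mode <- fit_posterior_mode(d)
  irls <- glm.fit(d$X, d$y, family = poisson())  # independent IRLS oracle
  expect_true(mode$converged)
  expect_lt(max(abs(mode$beta - irls$coefficients) /
                  pmax(abs(irls$coefficients), 1e-4)), 1e-6)
  # log-posterior is finite everywhere reasonable
  expect_true(is.finite(log_posterior(mode$beta, d, prior_spec("jeffreys"))))
})
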