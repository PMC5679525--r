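#' Sampler configuration
#'
#' Defaults follow the study protocol this pipeline implements: burn-in
#' 1000 iterations, 5000 retained iterations thinned by 10 (500 kept
#' draws per chain), and three chains with overdispersed starts so the
#' Gelman-Rubin diagnostic is defined.
#'
#' @param n_chains Number of chains (>= 2 when Gelman-Rubin diagnostics
#'   are wanted).
#' @param burn_in Burn-in iterations discarded before saving.
#' @param n_iter Post-burn-in iterations.
#' @param thin Thinning interval (kept draws = `n_iter / thin`).
#' @param seeds Integer seed per chain (default `11, 12, ...`).
#' @param bound Support bound for every coefficient: the sampler aborts
#'   if a coefficient reaches `|beta| = bound` (default 50 on the linear
#'   predictor scale).
#' @param init_jitter Overdispersion of the chain starts, in posterior
#'   SEs around the posterior mode (default 2).
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, burn_in = 1000L, n_iter = 5000L,
                           thin = 10L, seeds = NULL, bound = 50,
                           init_jitter = 2) {
  if (burn_in <= 0 || n_iter <= 0 || thin <= 0) {
    stop("burn_in, n_iter and thin must all be positive")
  }
  if (n_iter %% thin != 0) {
    stop("n_iter must be a multiple of thin")
  }
  if (is.null(seeds)) seeds <- 10L + seq_len(n_chains)
  if (length(seeds) != n_chains) stop("need one seed per chain")
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seeds = as.integer(seeds), bound = bound,
                 init_jitter = init_jitter),
            class = "sampler_config")
}

#' Draw from a univariate density by adaptive rejection Metropolis sampling
#'
#' Builds a piecewise-linear envelope of the log density from secants
#' through the abscissae, samples from the corresponding piecewise
#' exponential, refines the envelope on rejection, and applies a
#' Metropolis-Hastings correction so the draws leave the target invariant
#' even when it is not log-concave (for log-concave targets the
#' correction accepts with probability one and the draws are exact).
#'
#' @param log_density Function of one numeric argument returning the log
#'   density (up to a constant); may return `-Inf` inside the support.
#' @param support Numeric length-2 vector, the (finite) support bounds.
#' @param init_abscissae At least 3 distinct points inside the support
#'   bracketing the high-density region.
#' @param seed Integer seed (independent of R's RNG).
#' @param n Number of sequential draws (default 1).
#' @param x_init Starting state (default: middle abscissa).
#' @return Numeric vector of `n` draws.
#' @export
arms_draw <- function(log_density, support, init_abscissae, seed = 1L,
                      n = 1L, x_init = NULL) {
  stopifnot(length(support) == 2L, support[1] < support[2],
            length(init_abscissae) >= 3L)
  init <- sort(unique(as.numeric(init_abscissae)))
  if (is.null(x_init)) x_init <- init[ceiling(length(init) / 2)]
  f <- function(v) {
    r <- log_density(v)
    if (!is.finite(r)) r <- -1e300
    r
  }
  .arms_sample_cpp(f, as.integer(n), support[1], support[2], init,
                   x_init, as.integer(seed))
}

# Decorrelating reparameterization for the Gibbs sweep.  Columns other
# than the intercept are centred with the mode weights, and the
# day-level and stratum-level blocks are whitened by the Cholesky of
# their mode-information blocks.  For a complete day-by-stratum crossing
# this makes the information matrix (at the mode) essentially the
# identity, so single-coordinate updates mix almost independently, while
# every transformed column is still constant within days (or strata) and
# the grouped likelihood evaluation stays cheap.  Returns T with
# beta = T %*% theta.
build_reparam <- function(design, mode) {
  X <- design$X
  p <- ncol(X)
  w <- exp(pmin(drop(X %*% mode$beta), 700))
  info <- crossprod(X, X * w)
  nm <- colnames(X)
  ic <- if (!is.null(nm)) match("(Intercept)", nm) else NA_integer_
  if (!is.na(ic) && !all(X[, ic] == 1)) ic <- NA_integer_
  T1 <- diag(p)
  if (!is.na(ic)) {
    cmeans <- colSums(X * w) / sum(w)
    others <- setdiff(seq_len(p), ic)
    T1[ic, others] <- -cmeans[others]
  }
  info_c <- crossprod(T1, info %*% T1)
  bl <- design$blocks
  day <- c(bl$pm25, bl$weather, bl$interaction, bl$dow, bl$spline)
  strat <- c(bl$sex, bl$age, bl$occupation, bl$smoking)
  covered <- c(if (!is.na(ic)) ic, day, strat)
  rest <- setdiff(seq_len(p), covered)
  groups <- Filter(length, list(day = day, strat = c(strat, rest)))
  T2 <- diag(p)
  if (!is.na(ic)) T2[ic, ic] <- 1 / sqrt(info_c[ic, ic])
  for (b in groups) {
    Tb <- tryCatch(backsolve(chol(info_c[b, b, drop = FALSE]),
                             diag(length(b))),
                   error = function(e) diag(1 / sqrt(diag(info_c)[b]),
                                            length(b)))
    T2[b, b] <- Tb
  }
  T1 %*% T2
}

#' Run ARMS-within-Gibbs chains for the Bayesian Poisson GAM
#'
#' Samples the posterior of all coefficients (fixed effects and spline
#' block alike) by a systematic Gibbs sweep; each coordinate is updated
#' with an ARMS draw from its univariate full conditional.  To keep the
#' single-site sweep efficient the sampler works in a decorrelated
#' parameterization (weighted centring plus block whitening by the
#' information matrix at the posterior mode -- an invertible linear map,
#' so the posterior is unchanged) and maps every kept draw back to the
#' coefficient scale.  Chains start at the posterior mode plus
#' `init_jitter`-SD Gaussian jitter and are mutually independent given
#' their seeds.  Under `prior_spec("jeffreys")` the prior enters through
#' a per-sweep local linearization of `0.5 * log det(X' W X)` (see the
#' methods vignette); under a normal prior the exact Gaussian term is
#' used.
#'
#' @param design A `bgam_design` from [build_design_matrix()].
#' @param prior A `bgam_prior` from [prior_spec()].
#' @param config A `sampler_config`.
#' @param beta_init Optional matrix (chains x p) of starting values on
#'   the coefficient scale; defaults to jittered posterior-mode starts.
#' @return List of class `chain_set`: `draws` (array chains x kept x p
#'   with parameter dimnames), `config`, `prior`, `mode` (the Newton
#'   posterior mode fit), `tallies`.
#' @export
run_chains <- function(design, prior = prior_spec("jeffreys"),
                       config = sampler_config(), beta_init = NULL) {
  if (config$n_iter <= 0 || config$burn_in < 0 || config$thin <= 0) {
    stop("iterations, burn-in and thinning must be positive")
  }
  X <- design$X
  p <- ncol(X)
  mode_prior <- if (prior$type == "normal") prior else prior_spec("flat")
  mode <- fit_posterior_mode(design, mode_prior)
  if (!mode$converged) {
    warning("posterior-mode search did not fully converge; using last iterate")
  }
  Tmat <- build_reparam(design, mode)
  Xt <- X %*% Tmat
  mode_eta <- pmin(drop(X %*% mode$beta), 700)
  info_t <- crossprod(Xt, Xt * exp(mode_eta))
  sigma <- 1 / sqrt(pmax(diag(info_t), 1e-24))
  # sampled coordinates are offsets from the mode: beta = mode + T theta
  if (is.null(beta_init)) {
    theta_init <- local_seed(sum(config$seeds), {
      m <- vapply(seq_len(config$n_chains), function(ch) {
        config$init_jitter * sigma * rnorm(p)
      }, numeric(p))
      if (p == 1L) matrix(m, ncol = 1L) else t(m)
    })
  } else {
    stopifnot(nrow(beta_init) == config$n_chains, ncol(beta_init) == p)
    theta_init <- t(apply(beta_init, 1L, function(b) solve(Tmat, b - mode$beta)))
    if (p == 1L) theta_init <- matrix(theta_init, ncol = 1L)
  }

  columns <- lapply(seq_len(p), function(j) {
    u <- unique(Xt[, j])
    list(gidx = match(Xt[, j], u) - 1L, uvals = u)
  })
  ptype <- switch(prior$type, flat = 0L, normal = 1L, jeffreys = 2L)
  if (ptype == 1L) {
    pm_beta <- rep_len(prior$mean, p)
    psd <- rep_len(prior$sd, p)
    Dprec <- ifelse(is.finite(psd), 1 / psd^2, 0)
    Lambda <- crossprod(Tmat, (Tmat * Dprec))
    theta0 <- solve(Tmat, pm_beta - mode$beta)
  } else {
    Lambda <- matrix(0, p, p)
    theta0 <- numeric(p)
  }

  kept <- config$n_iter %/% config$thin
  # retain the unthinned post-burn-in chains for convergence diagnostics
  # (thinning is a storage economy; the PSRF is computed on full chains)
  # unless they would be unreasonably large
  keep_full <- config$n_iter * p <= 5e6
  draws <- array(NA_real_, dim = c(config$n_chains, kept, p),
                 dimnames = list(NULL, NULL, colnames(X)))
  full <- if (keep_full) {
    array(NA_real_, dim = c(config$n_chains, config$n_iter, p),
          dimnames = list(NULL, NULL, colnames(X)))
  }
  tallies <- vector("list", config$n_chains)
  sel <- seq(config$thin, config$n_iter, by = config$thin)
  for (ch in seq_len(config$n_chains)) {
    res <- .gibbs_poisson_cpp(as.numeric(design$y), Xt, mode_eta, columns,
                              theta_init[ch, ], sigma, config$bound, ptype,
                              theta0, Lambda, prior$refresh %||% 10L,
                              config$n_iter, config$burn_in, 1L,
                              config$seeds[ch])
    beta_draws <- sweep(res$draws %*% t(Tmat), 2L, mode$beta, `+`)
    draws[ch, , ] <- beta_draws[sel, , drop = FALSE]
    if (keep_full) full[ch, , ] <- beta_draws
    tallies[[ch]] <- res[c("mh_keep_current", "env_rejects")]
  }
  structure(list(draws = draws, full_draws = full, config = config,
                 prior = prior, mode = mode, parameters = colnames(X),
                 transform = Tmat, tallies = tallies),
            class = "chain_set")
}

#' Pooled posterior summary: mean and equal-tail 95% credible interval
#'
#' Pools the kept draws of all chains; the credible interval is the
#' empirical 2.5th/97.5th percentile (equal tails), which is invariant
#' under monotone transformations of the reporting scale.
#'
#' @param chains A `chain_set` (or matrix/array of draws).
#' @param level Credible level (default 0.95).
#' @return Data frame with `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(chains, level = 0.95) {
  m <- pooled_draws(chains)
  if (nrow(m) < 1L) stop("no draws to summarize")
  a <- (1 - level) / 2
  qs <- apply(m, 2L, quantile, probs = c(a, 1 - a), names = FALSE, type = 7)
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2L, sd),
             lower = qs[1L, ],
             upper = qs[2L, ],
             row.names = NULL)
}

#' Pool kept draws across chains
#'
#' Stacks the kept draws of all chains into one
#' (iterations x chains) by parameters matrix.
#'
#' @param chains A `chain_set`, a 3-d array (chains x iterations x
#'   parameters), or anything coercible to a matrix.
#' @return Numeric matrix with one column per parameter.
#' @export
pooled_draws <- function(chains) {
  if (inherits(chains, "chain_set")) chains <- chains$draws
  if (is.array(chains) && length(dim(chains)) == 3L) {
    d <- chains
    m <- matrix(aperm(d, c(2L, 1L, 3L)),
                nrow = dim(d)[1L] * dim(d)[2L], ncol = dim(d)[3L])
    colnames(m) <- dimnames(d)[[3L]]
    m
  } else {
    as.matrix(chains)
  }
}
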