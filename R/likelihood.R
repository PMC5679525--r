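eta_of <- function(design, beta) {
  drop(design$X %*% beta)
}

#' Exact Poisson log-likelihood of the mortality model
#'
#' `sum(-mu + y * eta - log(y!))` with `mu = exp(eta)`, evaluated
#' stably: the linear predictor is capped so a finite `eta` never
#' produces a non-finite log-likelihood.
#'
#' @param beta Coefficient vector matching the design columns.
#' @param design A `bgam_design` from [build_design_matrix()].
#' @param y Optional counts (defaults to `design$y`); must be
#'   nonnegative integers.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(beta, design, y = design$y) {
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be nonnegative integers")
  }
  eta <- pmin(eta_of(design, beta), 700)
  sum(-exp(eta) + y * eta - lfactorial(y))
}

#' Jeffreys' log-prior from the observed Fisher information
#'
#' For the Poisson log-linear model the observed information is
#' `X' W X` with `W = diag(mu)`, so Jeffreys' prior is proportional to
#' `det(X' W X)^(1/2)`.  Returns `0.5 * log det(X' W X)` (up to the
#' normalizing constant, which is improper).
#'
#' @param beta Coefficient vector.
#' @param design A `bgam_design` (must be full column rank).
#' @return Log prior density up to an additive constant.
#' @export
log_prior_jeffreys <- function(beta, design) {
  mu <- exp(eta_of(design, beta))
  if (any(!is.finite(mu))) stop("non-finite Poisson rates at this beta")
  M <- crossprod(design$X, design$X * mu)
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) stop("observed information is not positive definite")
  0.5 * as.numeric(ld$modulus)
}

#' Independent normal log-prior over selected coefficients
#'
#' Sums independent normal log-densities for the coefficients with a
#' finite prior standard deviation; coefficients with `NA` or infinite
#' `prior_sd` are left flat (contribute zero).
#'
#' @param beta Coefficient vector.
#' @param prior_mean,prior_sd Vectors recycled to `length(beta)`; `sd`
#'   must be positive where finite.
#' @return Log prior density.
#' @export
log_prior_normal <- function(beta, prior_mean = 0, prior_sd = Inf) {
  p <- length(beta)
  m <- rep_len(prior_mean, p)
  s <- rep_len(prior_sd, p)
  act <- is.finite(s)
  if (any(s[act] <= 0)) stop("prior_sd must be positive")
  if (!any(act)) return(0)
  sum(dnorm(beta[act], m[act], s[act], log = TRUE))
}

#' Prior specification for the Bayesian GAM
#'
#' @param type `"jeffreys"` (default, the non-informative prior from the
#'   observed Fisher information), `"flat"`, or `"normal"`.
#' @param mean,sd Normal prior mean/sd per coefficient (recycled; `Inf`
#'   sd = flat coordinate).  Ignored unless `type = "normal"`.
#' @param refresh For the sampler: how often (in Gibbs sweeps) the local
#'   linearization of the Jeffreys prior is refreshed (see the methods
#'   vignette); default every 10 sweeps.
#' @return List of class `bgam_prior`.
#' @export
prior_spec <- function(type = c("jeffreys", "flat", "normal"),
                       mean = 0, sd = Inf, refresh = 10L) {
  type <- match.arg(type)
  structure(list(type = type, mean = mean, sd = sd,
                 refresh = as.integer(refresh)),
            class = "bgam_prior")
}

#' Log-posterior of the mortality model
#'
#' @param beta Coefficient vector.
#' @param design A `bgam_design`.
#' @param prior A `bgam_prior` from [prior_spec()].
#' @return Log posterior density up to an additive constant.
#' @export
log_posterior <- function(beta, design, prior = prior_spec("flat")) {
  lp <- switch(prior$type,
               flat = 0,
               jeffreys = log_prior_jeffreys(beta, design),
               normal = log_prior_normal(beta, prior$mean, prior$sd))
  log_likelihood(beta, design) + lp
}

#' Posterior mode by Newton iteration
#'
#' Maximizes the log-posterior by damped Newton steps.  Under a flat
#' prior this is exactly the iteratively reweighted least squares fit of
#' the Poisson GLM; under the Jeffreys prior the gradient gains the
#' leverage term `0.5 * X' (h * mu)` from the derivative of
#' `0.5 * log det(X' W X)`; under a normal prior the Gaussian gradient
#' and curvature are added.
#'
#' @param design A `bgam_design`.
#' @param prior A `bgam_prior`.
#' @param beta_init Starting values (default: log mean rate intercept,
#'   zeros elsewhere).
#' @param max_iter,tol Newton iteration controls (`tol` on the step's
#'   max absolute coordinate change).
#' @return List: `beta` (mode), `fisher` (observed information at the
#'   mode, likelihood part), `se` (from the inverse information),
#'   `converged`, `iterations`.
#' @export
fit_posterior_mode <- function(design, prior = prior_spec("flat"),
                               beta_init = NULL, max_iter = 100L,
                               tol = 1e-9) {
  X <- design$X
  y <- design$y
  p <- ncol(X)
  beta <- beta_init %||% c(log(max(mean(y), 1e-8)), rep(0, p - 1L))
  pm <- rep_len(if (prior$type == "normal") prior$mean else 0, p)
  psd <- rep_len(if (prior$type == "normal") prior$sd else Inf, p)
  prec <- ifelse(is.finite(psd), 1 / psd^2, 0)
  objective <- function(b) log_posterior(b, design, prior)
  f_cur <- objective(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- exp(pmin(drop(X %*% beta), 700))
    Wx <- X * mu
    info <- crossprod(X, Wx) + diag(prec, p)
    grad <- drop(crossprod(X, y - mu)) - prec * (beta - pm)
    if (prior$type == "jeffreys") {
      R <- chol(info)
      XR <- X %*% backsolve(R, diag(p))
      h <- rowSums(XR^2)           # leverages x_i' M^{-1} x_i
      grad <- grad + 0.5 * drop(crossprod(X, h * mu))
    }
    step <- solve(info, grad)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      f_new <- objective(cand)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    beta <- beta + lambda * step
    f_cur <- objective(beta)
    if (max(abs(lambda * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- exp(pmin(drop(X %*% beta), 700))
  info <- crossprod(X, X * mu)
  se <- sqrt(diag(solve(info + diag(prec, p))))
  names(beta) <- colnames(X)
  list(beta = beta, fisher = info, se = se, converged = converged,
       iterations = it)
}
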