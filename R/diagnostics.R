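chain_matrix <- function(chains, ch) {
  d <- chains$draws
  m <- d[ch, , , drop = FALSE]
  dim(m) <- dim(d)[2:3]
  colnames(m) <- dimnames(d)[[3L]]
  m
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF per parameter from the between- and
#' within-chain variances, with the sampling-theory 97.5% upper bound.
#' Chains are considered converged when the upper bound is below 1.01.
#'
#' @param chains A `chain_set` or a 3-d array (chains x iterations x
#'   parameters) of equal-length chains.
#' @param threshold Convergence threshold on the upper bound (default
#'   1.01).
#' @return Data frame: `parameter`, `psrf`, `upper` (97.5% bound),
#'   `pass`.
#' @export
gelman_rubin <- function(chains, threshold = 1.01) {
  if (inherits(chains, "chain_set")) chains <- chains$draws
  stopifnot(length(dim(chains)) == 3L)
  m <- dim(chains)[1L]
  n <- dim(chains)[2L]
  if (m < 2L) stop("Gelman-Rubin diagnostics need at least 2 chains")
  if (n < 10L) stop("chains too short for a meaningful PSRF")
  p <- dim(chains)[3L]
  out <- data.frame(parameter = dimnames(chains)[[3L]] %||% paste0("b", seq_len(p)),
                    psrf = NA_real_, upper = NA_real_)
  for (j in seq_len(p)) {
    x <- matrix(chains[, , j], nrow = m)       # chains in rows
    xbar <- rowMeans(x)
    s2 <- apply(x, 1L, var)
    W <- mean(s2)
    B <- n * var(xbar)
    if (W <= 0) {
      out$psrf[j] <- 1
      out$upper[j] <- 1
      next
    }
    muhat <- mean(x)
    var_w <- var(s2) / m
    var_b <- 2 * B^2 / (m - 1)
    cov_wb <- (n / m) * (stats::cov(s2, xbar^2) - 2 * muhat * stats::cov(s2, xbar))
    V <- (n - 1) / n * W + (1 + 1 / m) * B / n
    var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
                2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
    df_adj <- if (is.finite(var_V) && var_V > 0) {
      df_V <- 2 * V^2 / var_V
      (df_V + 3) / (df_V + 1)
    } else 1
    psrf2 <- df_adj * V / W
    qF <- if (is.finite(var_w) && var_w > 0) {
      qf(0.975, m - 1, 2 * W^2 / var_w)
    } else {
      stats::qchisq(0.975, m - 1) / (m - 1)
    }
    upper2 <- df_adj * ((n - 1) / n + (1 + 1 / m) / n * (B / W) * qF)
    out$psrf[j] <- sqrt(max(psrf2, 0))
    out$upper[j] <- sqrt(max(upper2, psrf2, 0))
  }
  out$pass <- out$upper < threshold
  out
}

#' Autocorrelation, effective sample size and efficiency of MCMC draws
#'
#' Per parameter: the autocorrelation function of each chain (standard
#' autocovariance estimator after centring each chain at its own mean)
#' is averaged across chains; the pooled effective sample size is
#' `ESS = m*n / (1 + 2 * sum(rho_k))` with the sum truncated at the
#' first nonpositive paired sum `rho_{2t} + rho_{2t+1}` (Geyer's initial
#' positive sequence rule).  Efficiency is `ESS / (m*n)`.
#'
#' @param chains A `chain_set` or 3-d array (chains x iterations x
#'   parameters).
#' @param max_lag Largest lag retained in the reported ACF (default 50).
#' @return List of class `ess_report`: `table` (per parameter: `ess`,
#'   `efficiency`, `lag5` chain-averaged lag-5 ACF, `lag5_max_chain`
#'   largest per-chain |lag-5 ACF|, `constant` flag), `acf` (parameters
#'   x lags matrix of chain-averaged ACFs).
#' @export
ess_autocorr <- function(chains, max_lag = 50L) {
  if (inherits(chains, "chain_set")) chains <- chains$draws
  stopifnot(length(dim(chains)) == 3L)
  m <- dim(chains)[1L]
  n <- dim(chains)[2L]
  p <- dim(chains)[3L]
  if (m * n < 100L) stop("need at least 100 draws for ESS estimation")
  max_lag <- min(max_lag, n - 1L)
  acf_mat <- matrix(NA_real_, p, max_lag,
                    dimnames = list(dimnames(chains)[[3L]], NULL))
  tab <- data.frame(parameter = dimnames(chains)[[3L]] %||% paste0("b", seq_len(p)),
                    ess = NA_real_, efficiency = NA_real_, lag5 = NA_real_,
                    lag5_max_chain = NA_real_, constant = FALSE)
  for (j in seq_len(p)) {
    per_chain <- matrix(NA_real_, m, max_lag)
    constant <- TRUE
    for (ch in seq_len(m)) {
      x <- chains[ch, , j]
      if (sd(x) > 0) {
        constant <- FALSE
        a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1L]
        per_chain[ch, ] <- a
      }
    }
    if (constant) {
      tab$constant[j] <- TRUE
      next
    }
    rho <- colMeans(per_chain, na.rm = TRUE)
    acf_mat[j, ] <- rho
    # Geyer truncation on paired sums: initial positive sequence, with
    # the monotone adjustment (later pairs capped at earlier ones) to
    # stabilize the estimator
    npairs <- floor(max_lag / 2)
    cum <- 0
    prev <- Inf
    for (t in seq_len(npairs)) {
      ps <- rho[2 * t - 1] + rho[2 * t]
      if (!is.finite(ps) || ps <= 0) break
      ps <- min(ps, prev)
      prev <- ps
      cum <- cum + ps
    }
    ess <- m * n / (1 + 2 * cum)
    tab$ess[j] <- min(ess, m * n)  # cap at the number of kept draws
    tab$efficiency[j] <- tab$ess[j] / (m * n)
    tab$lag5[j] <- if (max_lag >= 5L) rho[5L] else NA_real_
    tab$lag5_max_chain[j] <- if (max_lag >= 5L) {
      max(abs(per_chain[, 5L]), na.rm = TRUE)
    } else NA_real_
  }
  structure(list(table = tab, acf = acf_mat, n_kept = m * n),
            class = "ess_report")
}

#' Daily standardized (Pearson) residuals of a fitted model
#'
#' Aggregates observed and fitted counts to daily totals and computes
#' Pearson residuals `(Y - mu) / sqrt(mu)`.  Under a well-specified
#' model with moderately large daily totals about 95% of residuals fall
#' in \[-2, 2\].
#'
#' @param design A `bgam_design`.
#' @param beta Coefficient vector (e.g. posterior means).
#' @return List of class `residual_report`: `residuals` (per day),
#'   `fraction_within_2`, `dates`, `flagged` (days with zero fitted rate
#'   but observed deaths).
#' @export
standardized_residuals <- function(design, beta) {
  mu <- exp(pmin(eta_of(design, beta), 700))
  y_day <- rowsum(as.numeric(design$y), design$day)
  mu_day <- rowsum(mu, design$day)
  flagged <- which(mu_day == 0 & y_day > 0)
  r <- (y_day - mu_day) / sqrt(pmax(mu_day, .Machine$double.eps))
  r <- as.numeric(r)
  structure(list(residuals = r,
                 fraction_within_2 = mean(abs(r) <= 2),
                 dates = sort(unique(design$dates)),
                 flagged = flagged),
            class = "residual_report")
}

#' Combined convergence report for a fitted chain set
#'
#' Bundles the Gelman-Rubin, autocorrelation/ESS and (optionally)
#' residual diagnostics with the pass rules used throughout the
#' pipeline: 97.5% PSRF bound < 1.01, chain-averaged |lag-5 ACF| < 0.1,
#' pooled ESS > 1000 and efficiency > 0.6.  The PSRF is evaluated on the
#' unthinned post-burn-in chains when the `chain_set` carries them
#' (thinning discards information the convergence check can use);
#' autocorrelation and ESS are evaluated on the thinned chains that are
#' actually summarized.
#'
#' @param chains A `chain_set`.
#' @param design Optional `bgam_design` for residual diagnostics.
#' @param ess_min,lag5_max,psrf_max,efficiency_min Pass thresholds.
#' @return List of class `convergence_report` with elements
#'   `gelman_rubin`, `ess`, `residuals` (or `NULL`), and `pass` flags.
#' @export
convergence_report <- function(chains, design = NULL, ess_min = 1000,
                               lag5_max = 0.1, psrf_max = 1.01,
                               efficiency_min = 0.6) {
  gr_input <- if (inherits(chains, "chain_set") &&
                  !is.null(chains$full_draws)) {
    chains$full_draws  # PSRF on the unthinned post-burn-in chains
  } else chains
  gr <- gelman_rubin(gr_input, threshold = psrf_max)
  er <- ess_autocorr(chains)
  res <- NULL
  if (!is.null(design)) {
    beta <- posterior_summary(chains)$mean
    res <- standardized_residuals(design, beta)
  }
  ok <- !er$table$constant
  pass <- list(
    psrf = all(gr$upper < psrf_max),
    lag5 = all(abs(er$table$lag5[ok]) < lag5_max, na.rm = TRUE),
    ess = all(er$table$ess[ok] > ess_min, na.rm = TRUE),
    efficiency = all(er$table$efficiency[ok] > efficiency_min, na.rm = TRUE),
    residuals = if (!is.null(res)) res$fraction_within_2 >= 0.95 else NA
  )
  structure(list(gelman_rubin = gr, ess = er, residuals = res, pass = pass),
            class = "convergence_report")
}
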