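#' Fit the Bayesian Poisson GAM to a (synthetic or real) study
#'
#' Builds the design matrix for the requested weather coding, runs the
#' ARMS-within-Gibbs sampler and returns the chains with their pooled
#' posterior summary.  Days with missing PM2.5 are dropped
#' (complete-case).
#'
#' @param study A list as returned by [simulate_study()] (`counts`,
#'   `pm`, `flags` and, for SWT coding, `features$swt`), or any list
#'   providing those elements for real data.
#' @param coding `"extreme"` (eight flags) or `"swt"` (five
#'   synoptic-type dummies).
#' @param with_interaction Include PM2.5-by-weather interactions.
#' @param prior A `bgam_prior`.
#' @param config A `sampler_config`.
#' @param basis Optional `spline_basis` (defaults to 5 knots/year on the
#'   analysis days).
#' @return List of class `bgam_fit`: `design`, `chains`, `summary`,
#'   `coding`, `with_interaction`.
#' @export
fit_bgam <- function(study, coding = c("extreme", "swt"),
                     with_interaction = TRUE, prior = prior_spec("jeffreys"),
                     config = sampler_config(), basis = NULL) {
  coding <- match.arg(coding)
  counts <- study$counts
  pm <- study$pm
  keep_dates <- pm$date[!is.na(pm$pm25)]
  counts <- counts[counts$date %in% keep_dates, , drop = FALSE]
  dates <- sort(unique(counts$date))
  weather <- if (coding == "extreme") {
    study$flags
  } else {
    if (is.null(study$features$swt)) {
      stop("SWT coding requested but study has no 'swt' labels")
    }
    study$features$swt[match(dates, study$features$date)]
  }
  design <- build_design_matrix(counts, pm, weather, basis = basis,
                                with_interaction = with_interaction)
  chains <- run_chains(design, prior = prior, config = config)
  structure(list(design = design, chains = chains,
                 summary = posterior_summary(chains), coding = coding,
                 with_interaction = with_interaction, prior = prior),
            class = "bgam_fit")
}

#' @export
print.bgam_fit <- function(x, ...) {
  cat("Bayesian Poisson GAM fit (", x$coding, " coding, ",
      if (x$with_interaction) "with" else "without", " interaction)\n", sep = "")
  cat(dim(x$chains$draws)[1L], "chains x", dim(x$chains$draws)[2L],
      "kept draws x", dim(x$chains$draws)[3L], "parameters\n")
  j <- x$design$blocks$pm25
  pi <- percent_increase(pooled_draws(x$chains)[, j])
  cat(sprintf("PM2.5 percent increase per 10 ug/m3: %.2f (%.2f, %.2f)\n",
              pi$estimate, pi$lower, pi$upper))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scaled-down parameter-recovery replicates
# ---------------------------------------------------------------------------

#' Strata and truth for scaled-down recovery replicates
#'
#' The coverage study uses a compact design: two sexes, two age groups
#' (40-64 and 65+) and one occupation, with the interaction effects set
#' to zero so the no-interaction model is exactly specified.
#'
#' @param pm25_pct_per10 True PM2.5 percent increase per 10 ug/m3.
#' @return List with `strata` and `truth`.
#' @export
recovery_config <- function(pm25_pct_per10 = 0.30) {
  sexes <- c("Male", "Female")
  ages <- c("40-64", "65+")
  g <- expand.grid(sex = sexes, age_group = ages, occupation = "Manufactory",
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  smoke <- matrix(c(34, 29.71, 1.0, 0.95), nrow = 2, byrow = TRUE,
                  dimnames = list(sexes, ages))
  g$smoking_rate <- smoke[cbind(g$sex, g$age_group)]
  g$sex <- factor(g$sex, levels = sexes)
  g$age_group <- factor(g$age_group, levels = ages)
  g$occupation <- factor(g$occupation)
  truth <- default_truth(pm25_pct_per10 = pm25_pct_per10)
  truth$interaction_effects[] <- 0
  truth$age_effects <- truth$age_effects["40-64"]
  truth$job_effects <- stats::setNames(numeric(0), character(0))
  list(strata = g, truth = truth)
}

#' One scaled-down replicate fit for coverage assessment
#'
#' Simulates a short study (default about 400 days) with a known PM2.5
#' coefficient and fits the no-interaction extreme-condition model with
#' a reduced sampler run (2 chains, burn-in 200, 1000 iterations,
#' thinned by 5).
#'
#' @param seed Replicate seed (drives data and chains).
#' @param n_days Study length in days.
#' @param pm25_pct_per10 True percent increase per 10 ug/m3.
#' @param prior A `bgam_prior`.
#' @return One-row data frame: `seed`, `estimate` (posterior-mean
#'   percent increase), `lower`, `upper` (CrI on the percent scale),
#'   `covered` (CrI contains the truth).
#' @export
recovery_replicate <- function(seed, n_days = 400L, pm25_pct_per10 = 0.30,
                               prior = prior_spec("jeffreys")) {
  rc <- recovery_config(pm25_pct_per10)
  calendar <- generate_calendar(as.Date("2012-01-01"),
                                as.Date("2012-01-01") + n_days - 1L)
  met <- simulate_meteorology(calendar, seed = seed * 17L + 1L)
  pm <- simulate_pm25(met, seed = seed * 17L + 2L, n_missing = 0L)
  flags <- compute_extreme_flags(met)
  features <- cbind(calendar, flags[, flag_names()])
  counts <- simulate_deaths(features, pm, rc$truth, rc$strata,
                            seed = seed * 17L + 3L)
  study <- list(counts = counts, pm = pm, flags = flags)
  cfg <- sampler_config(n_chains = 2L, burn_in = 200L, n_iter = 1000L,
                        thin = 5L, seeds = seed * 17L + c(7L, 8L))
  fit <- fit_bgam(study, coding = "extreme", with_interaction = FALSE,
                  prior = prior, config = cfg)
  j <- fit$design$blocks$pm25
  pi <- percent_increase(pooled_draws(fit$chains)[, j])
  data.frame(seed = seed, estimate = pi$estimate, lower = pi$lower,
             upper = pi$upper,
             covered = pi$lower <= pm25_pct_per10 & pm25_pct_per10 <= pi$upper)
}

#' Credible-interval coverage over replicate simulations
#'
#' @param n_reps Number of replicates.
#' @param seeds Integer seeds (default `1:n_reps`).
#' @param n_days,pm25_pct_per10,prior Passed to [recovery_replicate()].
#' @return List: `replicates` (per-replicate table), `coverage`
#'   (fraction of CrIs containing the truth), `bias` (mean posterior
#'   mean minus truth, percent points).
#' @export
run_recovery <- function(n_reps = 50L, seeds = seq_len(n_reps),
                         n_days = 400L, pm25_pct_per10 = 0.30,
                         prior = prior_spec("jeffreys")) {
  reps <- do.call(rbind, lapply(seeds, recovery_replicate, n_days = n_days,
                                pm25_pct_per10 = pm25_pct_per10,
                                prior = prior))
  list(replicates = reps,
       coverage = mean(reps$covered),
       bias = mean(reps$estimate) - pm25_pct_per10)
}

# ---------------------------------------------------------------------------
# End-to-end pipeline
# ---------------------------------------------------------------------------

#' Run the full pipeline and write its artifacts
#'
#' Simulate (or load) the study, compute weather features, fit the
#' requested model variants, run diagnostics and write all artifacts --
#' input CSVs, diagnostics JSON, effect tables and a run log -- to a
#' directory.  Deterministic given the seeds in the configuration.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `start`, `end` (dates), `seed`, `strata` (`"reduced"`/`"full"`),
#'   `codings` (subset of `c("extreme", "swt")`), `interactions`
#'   (logical vector), `prior` (`"jeffreys"`, `"flat"`, `"normal"`),
#'   `prior_mean`, `prior_sd`, `n_chains`, `burn_in`, `n_iter`, `thin`,
#'   `knots_per_year`, `out_dir`.
#' @return Invisible list with the study, fits, diagnostics and the
#'   effect table; artifacts under `config$out_dir` if given.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- list(start = "2012-01-01", end = "2014-12-31", seed = 1L,
              strata = "reduced", codings = "extreme", interactions = TRUE,
              prior = "jeffreys", prior_mean = 0, prior_sd = Inf,
              n_chains = 3L, burn_in = 1000L, n_iter = 5000L, thin = 10L,
              knots_per_year = 5, out_dir = NULL)
  cfg[names(config)] <- config
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  say("simulating study %s..%s (seed %d)", cfg$start, cfg$end, cfg$seed)
  study <- simulate_study(cfg$start, cfg$end, seed = cfg$seed,
                          strata_spec = default_strata(cfg$strata == "full"),
                          swt = "swt" %in% cfg$codings)
  prior <- prior_spec(cfg$prior, mean = cfg$prior_mean, sd = cfg$prior_sd)
  fits <- list()
  diags <- list()
  for (coding in cfg$codings) {
    for (wi in cfg$interactions) {
      tag <- paste0(coding, if (wi) "_interaction" else "_no_interaction")
      say("fitting %s model", tag)
      cfgs <- sampler_config(n_chains = cfg$n_chains, burn_in = cfg$burn_in,
                             n_iter = cfg$n_iter, thin = cfg$thin,
                             seeds = cfg$seed * 10L + seq_len(cfg$n_chains))
      fit <- fit_bgam(study, coding = coding, with_interaction = wi,
                      prior = prior, config = cfgs)
      fits[[tag]] <- fit
      rep <- convergence_report(fit$chains, fit$design)
      diags[[tag]] <- list(
        max_psrf_upper = max(rep$gelman_rubin$upper),
        min_ess = min(rep$ess$table$ess, na.rm = TRUE),
        max_lag5 = max(abs(rep$ess$table$lag5), na.rm = TRUE),
        residuals_within_2 = rep$residuals$fraction_within_2,
        pass = rep$pass)
      say("  PSRF upper max %.4f, min ESS %.0f",
          diags[[tag]]$max_psrf_upper, diags[[tag]]$min_ess)
    }
  }
  effects <- make_results_tables(fits)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study(study, file.path(cfg$out_dir, "data"))
    jsonlite::write_json(diags, file.path(cfg$out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(effects, file.path(cfg$out_dir, "effects.csv"),
              row.names = FALSE)
    for (tag in names(fits)) {
      write.csv(as.data.frame(pooled_draws(fits[[tag]]$chains)),
                file.path(cfg$out_dir, paste0("draws_", tag, ".csv")),
                row.names = FALSE)
    }
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  invisible(list(study = study, fits = fits, diagnostics = diags,
                 effects = effects, config = cfg))
}
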