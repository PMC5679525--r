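swt_levels <- function() {
  c("hot dry", "warm humid", "cold dry", "moderate dry", "moderate humid",
    "cold humid")
}

#' Build the Poisson GAM design matrix
#'
#' Assembles the model matrix of the mortality regression for the
#' stratum-day counts: intercept, PM2.5 (per ug/m3), the weather block
#' (eight non-exclusive extreme-condition flags, or five synoptic-type
#' dummies with cold humid as reference), optional PM2.5-by-weather
#' interactions, sex (male reference), age (65+ reference), occupation
#' (Manufactory reference), day of week (Sunday reference), smoking rate,
#' and the centred B-spline block for the smooth time trend.
#'
#' @param counts A `stratum_counts` data frame (one row per date-stratum,
#'   with `deaths`); days with missing PM2.5 must already be excluded.
#' @param pm A `pm_series` (or data frame with `date`, `pm25`).
#' @param weather An `extreme_flags` data frame, an `swt_labels` object,
#'   or a factor/character of synoptic labels aligned to the study dates.
#' @param basis A `spline_basis` for the study dates, or `NULL` to build
#'   one from the count dates with the defaults of
#'   [build_bspline_basis()].
#' @param with_interaction Include the PM2.5-by-weather block.
#' @param dow Optional factor of day-of-week per date; derived from the
#'   dates when `NULL`.
#' @return List of class `bgam_design`: `X`, `y`, `blocks` (named list of
#'   column indices), `dates` (per row), `day` (integer day index per
#'   row), `coding`, `basis`.
#' @export
build_design_matrix <- function(counts, pm, weather, basis = NULL,
                                with_interaction = TRUE, dow = NULL) {
  stopifnot(is.data.frame(counts))
  if (!all(counts$deaths >= 0) || any(counts$deaths != round(counts$deaths))) {
    stop("deaths must be nonnegative integers")
  }
  dates <- sort(unique(counts$date))
  pm_day <- pm$pm25[match(dates, pm$date)]
  if (anyNA(pm_day)) {
    stop("missing PM2.5 on ", sum(is.na(pm_day)),
         " included day(s); exclude missing-PM days before building the design")
  }
  if (is.null(basis)) basis <- build_bspline_basis(dates)
  if (is.null(dow)) {
    dow <- factor(weekdays(dates), levels = c("Sunday", "Monday", "Tuesday",
                                              "Wednesday", "Thursday",
                                              "Friday", "Saturday"))
  }

  # day-level weather columns
  if (inherits(weather, "swt_labels")) weather <- weather$label
  if (inherits(weather, "extreme_flags") ||
      (is.data.frame(weather) && all(flag_names() %in% names(weather)))) {
    wdates <- weather$date
    idx <- match(dates, wdates)
    if (anyNA(idx)) stop("weather flags do not cover all count dates")
    Wday <- vapply(flag_names(), function(f) as.numeric(weather[[f]][idx]),
                   numeric(length(dates)))
    coding <- "extreme"
  } else {
    lab <- factor(as.character(weather), levels = swt_levels())
    if (length(lab) == length(dates)) {
      labd <- lab
    } else {
      stop("SWT labels must align with the count dates (one label per day)")
    }
    if (anyNA(labd)) {
      stop("unseen SWT level(s): ",
           paste(setdiff(unique(as.character(weather)), swt_levels()),
                 collapse = ", "))
    }
    keep <- setdiff(swt_levels(), "cold humid")
    Wday <- vapply(keep, function(l) as.numeric(labd == l),
                   numeric(length(dates)))
    coding <- "swt"
  }

  # day-level fixed blocks
  dow_mm <- vapply(levels(dow)[-1L], function(l) as.numeric(dow == l),
                   numeric(length(dates)))
  spline_mm <- basis$centered
  if (nrow(spline_mm) != length(dates)) {
    if (length(basis$tnorm) == length(dates)) {
      spline_mm <- basis$centered
    } else {
      stop("spline basis rows (", nrow(spline_mm),
           ") do not match the number of days (", length(dates), ")")
    }
  }
  colnames(spline_mm) <- paste0("spline_", colnames(basis$basis)[-1L])

  day_block <- cbind(pm25 = pm_day, Wday,
                     if (with_interaction) {
                       inter <- pm_day * Wday
                       colnames(inter) <- paste0("pm25:", colnames(Wday))
                       inter
                     },
                     dow_mm, spline_mm)

  # stratum-level blocks
  check_factor <- function(x, name, ref_first = FALSE) {
    if (!is.factor(x)) x <- factor(x)
    x
  }
  sex <- check_factor(counts$sex)
  age <- check_factor(counts$age_group)
  occ <- check_factor(counts$occupation)
  if (!"65+" %in% levels(age)) stop("age_group must contain reference level '65+'")
  age <- stats::relevel(age, ref = "65+")
  if ("Manufactory" %in% levels(occ)) occ <- stats::relevel(occ, ref = "Manufactory")
  if (!"Male" %in% levels(sex)) stop("sex must contain reference level 'Male'")
  sex <- stats::relevel(sex, ref = "Male")
  drop_empty <- function(f) factor(f, levels = levels(f)[table(f)[levels(f)] > 0 |
                                                           seq_along(levels(f)) == 1L])
  age <- drop_empty(age); occ <- drop_empty(occ); sex <- drop_empty(sex)

  dummies <- function(f, prefix) {
    lv <- levels(f)[-1L]
    m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
    if (length(lv)) colnames(m) <- paste0(prefix, lv)
    m
  }
  strat_block <- cbind(dummies(sex, "sex"), dummies(age, "age"),
                       dummies(occ, "job"),
                       smoking = counts$smoking_rate)

  day_of_row <- match(counts$date, dates)
  X <- cbind(`(Intercept)` = 1, day_block[day_of_row, , drop = FALSE],
             strat_block)
  rownames(X) <- NULL

  nm <- colnames(X)
  idx_of <- function(pattern, exact = NULL) {
    if (!is.null(exact)) which(nm %in% exact) else grep(pattern, nm)
  }
  wcols <- colnames(Wday)
  blocks <- list(
    intercept = idx_of(exact = "(Intercept)"),
    pm25 = idx_of(exact = "pm25"),
    weather = idx_of(exact = wcols),
    interaction = if (with_interaction) idx_of(exact = paste0("pm25:", wcols)) else integer(0),
    sex = grep("^sex", nm),
    age = grep("^age", nm),
    occupation = grep("^job", nm),
    dow = idx_of(exact = levels(dow)[-1L]),
    smoking = idx_of(exact = "smoking"),
    spline = grep("^spline_", nm)
  )

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- nm[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  structure(list(X = X, y = as.integer(counts$deaths), blocks = blocks,
                 dates = counts$date, day = day_of_row, coding = coding,
                 with_interaction = with_interaction, basis = basis,
                 n_days = length(dates)),
            class = "bgam_design")
}
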