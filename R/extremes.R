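#' Names of the eight extreme-weather day-count flags
#' @return Character vector of the eight flag names.
#' @export
flag_names <- function() {
  c("hot", "cold", "hyperbaria", "hypobaria", "humid", "dry",
    "windy", "windless")
}

#' Compute the eight percentile day-count extreme-weather flags
#'
#' Day-count climate indices: a day is flagged extreme when the relevant
#' daily statistic falls strictly beyond the 10th/90th empirical
#' percentile of its reference distribution.  Hot/cold use daily max/min
#' temperature, hyperbaria/hypobaria max/min barometric pressure,
#' humid/dry mean relative humidity, and windy/windless mean wind speed.
#' Flags are non-exclusive: a day may carry several.
#'
#' Percentiles use the standard linear-interpolation empirical quantile
#' (`stats::quantile`, type 7) and strict inequalities, so a constant
#' series yields no flags.  By default thresholds are computed once from
#' the pooled full study period; `by_year = TRUE` recomputes them within
#' each calendar year.
#'
#' @param met A `met_matrix` from [simulate_meteorology()] or any list
#'   with `dates` and a `values` matrix holding columns `temp_min`,
#'   `temp_max`, `pressure_min`, `pressure_max`, `humidity_mean`,
#'   `wind_mean`.
#' @param lower_q,upper_q Percentile thresholds (defaults 0.10 / 0.90).
#' @param by_year Compute thresholds per calendar year instead of pooled.
#' @return Data frame of class `extreme_flags`: `date` plus eight logical
#'   columns, with the thresholds attached as attribute `"thresholds"`.
#' @export
compute_extreme_flags <- function(met, lower_q = 0.10, upper_q = 0.90,
                                  by_year = FALSE) {
  v <- met$values
  need <- c(hot = "temp_max", cold = "temp_min", hyperbaria = "pressure_max",
            hypobaria = "pressure_min", humid = "humidity_mean",
            dry = "humidity_mean", windy = "wind_mean", windless = "wind_mean")
  missing_cols <- setdiff(unique(need), colnames(v))
  if (length(missing_cols)) {
    stop("meteorology is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  side <- c(hot = "upper", cold = "lower", hyperbaria = "upper",
            hypobaria = "lower", humid = "upper", dry = "lower",
            windy = "upper", windless = "lower")
  groups <- if (by_year) format(as.Date(met$dates), "%Y") else rep("all", nrow(v))
  out <- data.frame(date = met$dates)
  thresholds <- list()
  for (fl in flag_names()) {
    x <- v[, need[[fl]]]
    q <- if (side[[fl]] == "upper") upper_q else lower_q
    thr <- tapply(x, groups, quantile, probs = q, names = FALSE, type = 7)
    thr_day <- thr[groups]
    out[[fl]] <- if (side[[fl]] == "upper") x > thr_day else x < thr_day
    thresholds[[fl]] <- thr
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("extreme_flags", "data.frame")
  out
}
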