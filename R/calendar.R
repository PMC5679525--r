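#' Build a daily study calendar
#'
#' Expands an inclusive date range into one row per day with the covariates
#' the mortality model needs: day of week (Sunday first, the reference level
#' used in the regression), a 1-based year index, and calendar time rescaled
#' to \[0, 1\] for the spline smoother.
#'
#' @param start_date,end_date `Date` or ISO-8601 string; both ends inclusive.
#' @return A data frame with columns `date`, `dow` (factor, Sunday..Saturday),
#'   `year_index`, `doy` (day of year) and `tnorm` (time mapped to \[0, 1\]).
#' @examples
#' cal <- generate_calendar("2012-01-01", "2014-12-31")
#' nrow(cal)  # 1096 days
#' @export
generate_calendar <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("start_date and end_date must be valid dates")
  }
  if (start_date > end_date) {
    stop("start_date must not be after end_date")
  }
  dates <- seq(start_date, end_date, by = "day")
  dow <- factor(weekdays(dates, abbreviate = FALSE),
                levels = c("Sunday", "Monday", "Tuesday", "Wednesday",
                           "Thursday", "Friday", "Saturday"))
  years <- as.integer(format(dates, "%Y"))
  n <- length(dates)
  data.frame(
    date = dates,
    dow = dow,
    year_index = years - years[1L] + 1L,
    doy = as.integer(format(dates, "%j")),
    tnorm = if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  )
}
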