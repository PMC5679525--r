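#' Cubic B-spline basis for the smooth time trend
#'
#' Builds the B-spline basis for the calendar-time smoother S(t).  Time is
#' mapped to \[0, 1\]; interior knots are equally spaced over the span
#' (by default 5 knots per study year, i.e. 15 interior knots for a
#' three-year study), and boundary knots sit at the span ends with
#' multiplicity `degree + 1`.  The uncentered basis has
#' `n_interior + degree + 1` columns and satisfies the partition of unity
#' on the interior.  For use alongside an intercept the object also
#' carries an identifiable version: the first column is dropped and the
#' remaining columns are centred to mean zero.
#'
#' @param dates `Date` vector (>= 2 distinct dates).
#' @param knots_per_year Interior knots per 365.25 days (default 5).
#' @param degree Spline degree (default 3, cubic).
#' @param n_interior Optional explicit interior-knot count, overriding
#'   `knots_per_year`.
#' @return List of class `spline_basis`: `basis` (uncentered), `centered`
#'   (identifiable basis actually entering the design), `offsets` (column
#'   means removed), `knots` (interior, on \[0, 1\]), `degree`, `tnorm`.
#' @export
build_bspline_basis <- function(dates, knots_per_year = 5, degree = 3,
                                n_interior = NULL) {
  dates <- as.Date(dates)
  ud <- sort(unique(dates))
  if (length(ud) < 2L) stop("need at least two distinct dates")
  span <- as.numeric(ud[length(ud)] - ud[1L]) + 1
  if (is.null(n_interior)) {
    n_interior <- round(knots_per_year * span / 365.25)
  }
  n_interior <- as.integer(n_interior)
  if (n_interior < 0) stop("number of interior knots must be >= 0")
  if (n_interior >= length(ud)) {
    stop("interior knots (", n_interior, ") must be fewer than distinct dates (",
         length(ud), ")")
  }
  tnorm <- as.numeric(dates - ud[1L]) / max(as.numeric(ud[length(ud)] - ud[1L]), 1)
  interior <- if (n_interior > 0) seq_len(n_interior) / (n_interior + 1) else numeric(0)
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  basis <- splines::splineDesign(knots = knots, x = tnorm, ord = degree + 1L,
                                 outer.ok = FALSE)
  colnames(basis) <- paste0("s", seq_len(ncol(basis)))
  if (ncol(basis) > 1L) {
    reduced <- basis[, -1L, drop = FALSE]
    offsets <- colMeans(reduced)
    centered <- sweep(reduced, 2L, offsets)
  } else {
    centered <- basis
    offsets <- rep(0, ncol(basis))
  }
  structure(list(basis = basis, centered = centered, offsets = offsets,
                 knots = interior, degree = degree, tnorm = tnorm,
                 origin = ud[1L], span_days = span),
            class = "spline_basis")
}
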