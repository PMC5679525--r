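# Shared fixtures built in code (no stored data).

# A short simulated study, cached per session for speed.
tiny_study <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3, end = "2012-06-30") {
    key <- paste(seed, end)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_study("2012-01-01", end, seed = seed)
    }
    cache[[key]]
  }
})

# Intercept-only design on given counts (for conjugate checks).
intercept_design <- function(y) {
  n <- length(y)
  structure(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                 y = as.integer(y), day = seq_len(n),
                 dates = as.Date("2012-01-01") + seq_len(n) - 1,
                 blocks = list(intercept = 1L), n_days = n),
            class = "bgam_design")
}

# Independent Cox-de Boor recursion (textbook form), used as the oracle
# for the spline basis.
coxdeboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B <- function(i, d, t) {
    if (d == 0) {
      # right-closed at the final knot so the basis sums to 1 at t = 1
      hi <- knots[i + 1L]
      lo <- knots[i]
      if (hi == knots[length(knots)] && t == hi) return(as.numeric(t >= lo))
      return(as.numeric(t >= lo & t < hi))
    }
    a <- 0
    den1 <- knots[i + d] - knots[i]
    if (den1 > 0) a <- (t - knots[i]) / den1 * B(i, d - 1L, t)
    b <- 0
    den2 <- knots[i + d + 1L] - knots[i + 1L]
    if (den2 > 0) b <- (knots[i + d + 1L] - t) / den2 * B(i + 1L, d - 1L, t)
    a + b
  }
  out <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) out[, j] <- vapply(x, function(t) B(j, degree, t), 0)
  out
}
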