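# Shape-preserving cubic Hermite interpolation (Fritsch-Carlson slope
# limiting) with controllable end slopes. Used for the along-path free-energy
# profile, where the control points must be exact local extrema of the
# interpolant (zero slope at interior extrema) and the path ends must be
# stationary, and for the waypoint coordinate splines. C^1 by construction.

# Fritsch-Carlson limited slopes. ends: "zero" clamps both end slopes to 0,
# "secant" uses the one-sided secant.
.fc_slopes <- function(x, y, ends = c("zero", "secant")) {
  ends <- match.arg(ends)
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      d0 <- delta[i - 1]; d1 <- delta[i]
      if (d0 * d1 <= 0) {
        m[i] <- 0  # local extremum of the data: interpolant extremum here
      } else {
        w1 <- 2 * h[i] + h[i - 1]
        w2 <- h[i] + 2 * h[i - 1]
        m[i] <- (w1 + w2) / (w1 / d0 + w2 / d1)
      }
    }
  }
  if (ends == "secant") {
    m[1] <- delta[1]
    m[n] <- delta[n - 1]
  }
  m
}

# Returns a vectorized evaluator function on [min(x), max(x)] (clamped
# outside). deriv = 0 or 1.
.hermite_fun <- function(x, y, ends = "zero") {
  stopifnot(length(x) == length(y), length(x) >= 2, !is.unsorted(x),
            all(diff(x) > 0))
  m <- .fc_slopes(x, y, ends)
  h <- diff(x)
  force(y)
  function(s, deriv = 0) {
    s <- pmin(pmax(s, x[1]), x[length(x)])
    i <- findInterval(s, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(x) - 1L)
    t <- (s - x[i]) / h[i]
    y0 <- y[i]; y1 <- y[i + 1L]; m0 <- m[i] * h[i]; m1 <- m[i + 1L] * h[i]
    if (deriv == 0) {
      h00 <- (1 + 2 * t) * (1 - t)^2
      h10 <- t * (1 - t)^2
      h01 <- t^2 * (3 - 2 * t)
      h11 <- t^2 * (t - 1)
      h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1
    } else {
      d00 <- 6 * t * (t - 1)
      d10 <- (1 - t) * (1 - 3 * t)
      d01 <- -6 * t * (t - 1)
      d11 <- t * (3 * t - 2)
      (d00 * y0 + d10 * m0 + d01 * y1 + d11 * m1) / h[i]
    }
  }
}
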