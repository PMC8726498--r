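# Small finite-difference and quadrature kernels shared by the mechanics,
# kinetics and transport code. All operate on uniformly spaced grids (the
# solver works on a fixed scaled coordinate xi = r/R, which is uniform).

# Second-order first derivative on a uniform grid: central differences on
# interior nodes, one-sided three-point stencils at the ends.
fd_gradient <- function(f, h) {
  n <- length(f)
  if (n < 3L) stop("fd_gradient needs at least 3 nodes")
  g <- numeric(n)
  g[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * h)
  g[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  g[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h)
  g
}

# Trapezoidal quadrature on a (possibly nonuniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoid from x[1]; result[1] = 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Integral of f(r) r^2 dr over the grid, treating f as piecewise linear
# against the exact r^2 weight (exact for linear f; plain trapezoid of f*r^2
# loses all relative accuracy on the first cell at the origin).
integrate_r2 <- function(f, r) {
  n <- length(r)
  a <- r[-n]
  b <- r[-1]
  w_a <- b * (b^3 - a^3) / 3 - (b^4 - a^4) / 4
  w_b <- (b^4 - a^4) / 4 - a * (b^3 - a^3) / 3
  sum((f[-n] * w_a + f[-1] * w_b) / (b - a))
}

# Thomas algorithm for a tridiagonal system with sub-diagonal `a` (length
# n-1), diagonal `b` (length n) and super-diagonal `cc` (length n-1).
solve_tridiag <- function(a, b, cc, d) {
  n <- length(b)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  cp[1] <- cc[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    denom <- b[i] - a[i - 1] * (if (i > 1) cp[i - 1] else 0)
    if (i < n) cp[i] <- cc[i] / denom
    dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}
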