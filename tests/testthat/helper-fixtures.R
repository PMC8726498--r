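# Shared fixtures: small, fast parameter sets and generators used across the
# suite. All randomness is seeded locally inside the tests that use it.

# Regime with uniform nutrient and no volume loss or feedback: the radius
# grows exactly exponentially, R(t) = R0 exp(lambda0 t / 3).
exponential_growth_params <- function(beta = 0.4) {
  spheroid_params(L = 1e6, lambda_Ac = 0, Delta_A = 0, gamma_A = 0,
                  gamma_c = 0, beta = beta)
}

# A random admissible reference map on [0, R]: smooth, strictly increasing,
# y(0) = 0 (slope bounded in [0.25, 1.75] so finite differences stay
# positive).
random_reference_map <- function(grid_r) {
  R <- grid_r[length(grid_r)]
  k <- sample(1:3, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  a <- stats::runif(1, 0.6, 1.4)
  b <- stats::runif(1, 0, 0.35)
  # antiderivative of a + b sin(2 pi k r / R + phi)
  w <- 2 * pi * k / R
  a * grid_r - (b / w) * (cos(w * grid_r + phi) - cos(phi))
}

# Manually assembled elastic stress profile (for operations that only read
# sigma_rr / sigma_tt / grid_r).
manual_stress <- function(grid_r, sigma_rr, sigma_tt) {
  structure(list(grid_r = grid_r, sigma_rr = sigma_rr, sigma_tt = sigma_tt,
                 W = 0.5 * (sigma_rr + 2 * sigma_tt - 3)),
            class = "stress_profile")
}

# Calibration study conditions: free suspension plus one gel, small spheroid
# so forward runs stay fast.
calib_conditions <- function(c_H = 0.6, R0 = 50) {
  list(free = confinement("none"),
       gel = confinement("gel", c_H = c_H, R0 = R0))
}

calib_times <- c(2, 4, 7, 11, 16, 22, 28)
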