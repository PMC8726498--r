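test_that("reference map relaxes pointwise toward the current coordinate", {
  # v = 0: y(r,t) = r + (y0 - r) exp(-beta t), here y0 = 0.5 r, beta = 1, t = 1
  st <- tissue_state(R = 1, N = 100)
  r <- grid_r(st)
  st$y <- 0.5 * r
  nsteps <- 50
  dt <- 1 / nsteps
  for (i in seq_len(nsteps))
    st$y <- advance_reference_map(st, rep(0, 100), beta = 1, dt, dRdt = 0)
  expect_equal(st$y, r * (1 - 0.5 * exp(-1)), tolerance = 1e-10)
})

test_that("displacement decays at exactly the relaxation rate", {
  beta <- 0.7
  st <- tissue_state(R = 1, N = 100)
  r <- grid_r(st)
  st$y <- 0.6 * r + 0.4 * r^2
  u0 <- max(abs(r - st$y))
  t_end <- 5 / beta
  dt <- 0.02
  nsteps <- round(t_end / dt)
  for (i in seq_len(nsteps))
    st$y <- advance_reference_map(st, rep(0, 100), beta, dt, dRdt = 0)
  rate <- -log(max(abs(r - st$y)) / u0) / (nsteps * dt)
  expect_lt(abs(rate - beta) / beta, 0.01)
})

test_that("without relaxation the reference coordinate rides the flow", {
  # uniform expansion v = k r / 3 from an unstressed start: y = r exp(-k t/3)
  k <- 0.6
  N <- 150
  st <- tissue_state(R = 1, N = N)
  t <- 0
  dt <- 0.01
  for (i in 1:100) {
    r <- grid_r(st)
    v <- k * r / 3
    st$y <- advance_reference_map(st, v, beta = 0, dt, dRdt = v[N])
    t <- t + dt
    st$R <- exp(k * t / 3)   # exact boundary motion for this flow
  }
  expect_equal(st$y, grid_r(st) * exp(-k * t / 3), tolerance = 1e-3)
})

test_that("advected reference values are conserved along characteristics", {
  # beta = 0, stationary boundary: y(r(t), t) must equal y(r(0), 0) where
  # r(t) solves dr/dt = v(r); the oracle tracks characteristics with RK4
  N <- 400
  st <- tissue_state(R = 1, N = N)
  vfun <- function(x) 0.05 * sin(pi * x)
  r <- grid_r(st)
  v <- vfun(r)
  t_end <- 1
  dt <- 0.4 * (r[2] - r[1]) / max(abs(v))
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  for (i in seq_len(nsteps))
    st$y <- advance_reference_map(st, v, beta = 0, dt, dRdt = 0)
  for (r0 in c(0.2, 0.5, 0.8)) {
    x <- r0
    m <- 2000
    ddt <- t_end / m
    for (i in seq_len(m)) {
      k1 <- vfun(x); k2 <- vfun(x + ddt / 2 * k1)
      k3 <- vfun(x + ddt / 2 * k2); k4 <- vfun(x + ddt * k3)
      x <- x + ddt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    drift <- abs(stats::approx(r, st$y, xout = x)$y - r0)
    expect_lt(drift / t_end, 1e-3)
  }
})

test_that("CFL violations in transport are rejected", {
  st <- tissue_state(R = 1, N = 50)
  v <- 10 * grid_r(st) * (1 - st$xi)  # large mesh-relative velocity
  expect_error(advance_reference_map(st, v, beta = 0, dt = 0.5, dRdt = 0),
               "CFL")
})

test_that("matched division and volume rates keep the density uniform", {
  st <- tissue_state(R = 40, N = 100)
  r <- grid_r(st)
  lam_net <- 0.5 - 0.9 * (r / 40)^2          # arbitrary smooth profile
  rates <- list(lam_net_cell = lam_net, lam_net_vol = lam_net)
  v <- radial_velocity(lam_net, r)
  for (i in 1:40)
    st$rho_c <- advance_cell_density(st, v, rates, D = 1, dt = 0.05)
  expect_equal(st$rho_c, rep(1, 100), tolerance = 1e-8)
})

test_that("no-flux diffusion conserves the discrete cell number", {
  st <- tissue_state(R = 10, N = 120)
  r <- grid_r(st)
  st$rho_c <- 1 + 0.8 * exp(-((r - 4) / 2)^2)
  n0 <- total_cell_number(st)
  zero <- rep(0, 120)
  rates <- list(lam_net_cell = zero, lam_net_vol = zero)
  for (i in 1:60)
    st$rho_c <- advance_cell_density(st, zero, rates, D = 2, dt = 0.05)
  expect_lt(abs(total_cell_number(st) - n0) / n0, 1e-10)
  expect_true(all(st$rho_c > 0))
  # diffusion flattens the bump monotonically in range
  expect_lt(max(st$rho_c), 1.8)
})

test_that("uniform reaction reproduces the scalar growth ODE", {
  st <- tissue_state(R = 5, N = 60)
  g <- 0.23
  rates <- list(lam_net_cell = rep(g, 60), lam_net_vol = rep(0, 60))
  zero <- rep(0, 60)
  for (i in 1:50)
    st$rho_c <- advance_cell_density(st, zero, rates, D = 0, dt = 0.04)
  expect_equal(st$rho_c, rep(exp(g * 2), 60), tolerance = 1e-6)
})

test_that("regrid preserves linear fields exactly and converges fast", {
  st <- tissue_state(R = 2, N = 100)
  expect_identical(regrid(st, 2), st)
  r <- grid_r(st)
  st$y <- 0.7 * r
  st$rho_c <- 1 + 0.2 * r
  st2 <- regrid(st, 1.5)
  expect_equal(st2$y, 0.7 * grid_r(st2), tolerance = 1e-12)
  expect_equal(st2$rho_c, 1 + 0.2 * grid_r(st2), tolerance = 1e-12)
  expect_error(regrid(st, -1), "positive")
  # smooth field: halving the spacing shrinks the error at least 4x
  err <- vapply(c(100, 200), function(N) {
    s <- tissue_state(R = 2, N = N)
    rr <- grid_r(s)
    s$rho_c <- 1 + 0.5 * exp(-(rr - 1)^2)
    s2 <- regrid(s, 1.6)
    rn <- grid_r(s2)
    max(abs(s2$rho_c - (1 + 0.5 * exp(-(rn - 1)^2))))
  }, numeric(1))
  expect_gt(err[1] / err[2], 4)
})

test_that("transported fields converge under grid refinement", {
  p <- spheroid_params()
  sols <- lapply(c(100, 200, 400), function(N) {
    res <- run_spheroid(p, t_end = 5, R0 = 100, N = N, dt_max = 10 / N,
                        snapshot_times = c(0, 5))
    res$state
  })
  xi <- sols[[1]]$xi
  err <- vapply(1:2, function(i) {
    y_i <- stats::approx(sols[[i]]$xi, sols[[i]]$y, xout = xi)$y
    y_f <- stats::approx(sols[[3]]$xi, sols[[3]]$y, xout = xi)$y
    rho_i <- stats::approx(sols[[i]]$xi, sols[[i]]$rho_c, xout = xi)$y
    rho_f <- stats::approx(sols[[3]]$xi, sols[[3]]$rho_c, xout = xi)$y
    max(max(abs(y_i - y_f)) / sols[[3]]$R, max(abs(rho_i - rho_f)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.9)  # order >= 1
})
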