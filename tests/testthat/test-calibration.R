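test_that("AICc follows the Gaussian least-squares form", {
  expect_equal(aicc(10, 20, 0), 20 * log(0.5))
  expect_equal(aicc(20, 20, 2), 4 + 12 / 17)   # n ln(1) + 2k + 2k(k+1)/(n-k-1)
  expect_error(aicc(5, 4, 3), "AICc undefined")
})

test_that("objective vanishes on noise-free synthetic data", {
  p <- spheroid_params()
  cache <- new.env(parent = emptyenv())
  obs <- generate_observations(p, calib_conditions(), calib_times,
                               radius_sd = 0, density_sd = 0, seed = 1,
                               R0 = 50, N = 60, cache = cache)
  obs$radius_obs$sd <- 2       # avoid zero-sd normalization
  obs$density_obs$sd <- 0.03
  expect_lt(objective(p, obs, R0 = 50, N = 60, cache = cache), 1e-16)
  # perturbing a parameter strictly increases the objective
  worse <- objective(update_params(p, beta = 0.8), obs, R0 = 50, N = 60,
                     cache = cache)
  expect_gt(worse, 1)
})

test_that("objective is invariant to observation ordering and degenerates
           to radius-only without density data", {
  p <- spheroid_params()
  cache <- new.env(parent = emptyenv())
  obs <- generate_observations(p, calib_conditions(), calib_times,
                               radius_sd = 2, density_sd = 0.03, seed = 3,
                               R0 = 50, N = 60, cache = cache)
  o1 <- objective(p, obs, R0 = 50, N = 60, cache = cache)
  perm <- obs
  set.seed(1)
  perm$radius_obs <- perm$radius_obs[sample(nrow(perm$radius_obs)), ]
  expect_equal(objective(p, perm, R0 = 50, N = 60, cache = cache), o1)
  radius_only <- obs
  radius_only$density_obs <- obs$density_obs[0, ]
  o_r <- objective(p, radius_only, R0 = 50, N = 60, cache = cache)
  expect_lt(o_r, o1)
  # the dropped term is exactly the density residual
  dens_term <- o1 - o_r
  expect_gt(dens_term, 0)
})

test_that("synthetic observations are reproducible and unbiased", {
  p <- spheroid_params()
  cache <- new.env(parent = emptyenv())
  a <- generate_observations(p, calib_conditions(), calib_times,
                             radius_sd = 2, seed = 11, R0 = 50, N = 60,
                             cache = cache)
  b <- generate_observations(p, calib_conditions(), calib_times,
                             radius_sd = 2, seed = 11, R0 = 50, N = 60,
                             cache = cache)
  expect_identical(a$radius_obs, b$radius_obs)
  expect_identical(a$density_obs, b$density_obs)
  truth <- generate_observations(p, calib_conditions(), calib_times,
                                 radius_sd = 0, density_sd = 0, seed = 1,
                                 R0 = 50, N = 60, cache = cache)
  # empirical residual sd over replicates approaches the nominal sd
  resid <- unlist(lapply(1:100, function(s) {
    o <- generate_observations(p, calib_conditions(), calib_times,
                               radius_sd = 5, density_sd = 0, seed = s,
                               R0 = 50, N = 60, cache = cache)
    o$radius_obs$radius - truth$radius_obs$radius
  }))
  expect_lt(abs(stats::sd(resid) - 5) / 5, 0.1)
})

test_that("grid search is deterministic and honors singleton grids", {
  p <- spheroid_params()
  cache <- new.env(parent = emptyenv())
  obs <- generate_observations(p, calib_conditions(), calib_times,
                               radius_sd = 2, seed = 5, R0 = 50, N = 60,
                               cache = cache)
  f1 <- grid_search(p, list(beta = 0.4), obs, R0 = 50, N = 60, cache = cache)
  expect_equal(f1$best$beta, 0.4)
  expect_equal(nrow(f1$surface), 1L)
  expect_equal(f1$objective, objective(p, obs, R0 = 50, N = 60,
                                       cache = cache))
  f2 <- grid_search(p, list(beta = 0.4), obs, R0 = 50, N = 60, cache = cache)
  expect_identical(f1$surface, f2$surface)
  # duplicated grid values: tie broken by the first index
  f3 <- grid_search(p, list(beta = c(0.4, 0.4)), obs, R0 = 50, N = 60,
                    cache = cache)
  expect_equal(f3$per_variant$fit$index, 1L)
})

test_that("model selection identifies data generated without feedback", {
  p_true <- spheroid_params(gamma_A = 0)   # no stress feedback in the truth
  cache <- new.env(parent = emptyenv())
  base <- spheroid_params()                # candidate model keeps feedback
  wins <- vapply(1:3, function(s) {
    obs <- generate_observations(p_true, calib_conditions(), calib_times,
                                 radius_sd = 2, density_sd = 0.03, seed = s,
                                 R0 = 50, N = 60, cache = cache)
    fit <- grid_search(base, list(beta = c(0.4, 0.8),
                                  `c_H:gel` = c(0.3, 0.6)),
                       obs, variants = feedback_variants(2),
                       R0 = 50, N = 60, cache = cache)
    fit$best_variant == "no_feedback"
  }, logical(1))
  expect_true(all(wins))
})
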