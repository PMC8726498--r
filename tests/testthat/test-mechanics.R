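test_that("elastic stress of the identity map is the isotropic unit state", {
  r <- seq(0, 10, length.out = 80)
  s <- elastic_stress(r, r)
  expect_equal(s$sigma_rr, rep(1, 80), tolerance = 1e-12)
  expect_equal(s$sigma_tt, rep(1, 80), tolerance = 1e-12)
  expect_equal(s$W, rep(0, 80), tolerance = 1e-12)
  # with no external force the total stress vanishes after pressure recovery
  p <- pressure_field(s, rep(0, 80), alpha = 1e-3, F_ext = 0)
  s <- total_stress(s, p)
  expect_equal(s$sigma_rr_tot, rep(0, 80), tolerance = 1e-12)
  expect_equal(s$sigma_tt_tot, rep(0, 80), tolerance = 1e-12)
})

test_that("stress components are the stated powers of the stretch ratio", {
  # q = (dy/dr)/(y/r) = 2 gives sigma_rr = 2^(-4/3), sigma_tt = 2^(2/3)
  expect_equal(2^(-4 / 3), 0.39685, tolerance = 1e-4)
  expect_equal(2^(2 / 3), 1.58740, tolerance = 1e-4)
  # realized on a linear-through-zero map with a quadratic part: at the
  # center y/r -> dy/dr so q = 1 exactly (isotropy at the origin)
  r <- seq(0, 1, length.out = 101)
  s <- elastic_stress(0.5 * r + 0.3 * r^2, r)
  expect_equal(s$sigma_rr[1], s$sigma_tt[1], tolerance = 1e-10)
  expect_gt(min(s$sigma_rr), 0)
  expect_gt(min(s$sigma_tt), 0)
})

test_that("sigma_rr * sigma_tt^2 = 1 for random admissible maps", {
  set.seed(42)
  r <- seq(0, 5, length.out = 64)
  for (i in 1:25) {
    y <- random_reference_map(r)
    s <- elastic_stress(y, r)
    expect_lt(max(abs(s$sigma_rr * s$sigma_tt^2 - 1)), 1e-10)
  }
})

test_that("tangled reference maps are rejected", {
  r <- seq(0, 1, length.out = 20)
  y <- r
  y[10] <- y[12]   # locally non-monotone
  expect_error(elastic_stress(y, r), "non-monotone|invalid")
  expect_error(elastic_stress(r + 0.5, r), "vanish at the center")
})

test_that("pressure recovery reproduces a manufactured solution", {
  r <- seq(0, 2, length.out = 201)
  R <- 2
  s <- manual_stress(r, 1 + r^2, rep(1, 201))
  # dp/dr = 2r + (2/r) r^2 = 4r  =>  p = p(R) - 2 (R^2 - r^2)
  p <- pressure_field(s, rep(0, 201), alpha = 0, F_ext = 0)
  p_exact <- (1 + R^2) - 2 * (R^2 - r^2)
  expect_equal(p, p_exact, tolerance = 1e-10)
})

test_that("boundary force balance sets p(R) = sigma_rr(R) + F_ext", {
  r <- seq(0, 1, length.out = 50)
  s <- manual_stress(r, rep(1, 50), rep(1, 50))
  P <- 0.7
  p <- pressure_field(s, rep(0, 50), alpha = 0, F_ext = P)
  expect_equal(p, rep(1 + P, 50), tolerance = 1e-12)
  s <- total_stress(s, p)
  expect_equal(s$sigma_rr_tot[50], -P, tolerance = 1e-12)
})

test_that("gel confinement force follows the cavity-expansion closed form", {
  gel <- confinement("gel", c_H = 1, R0 = 1)
  expect_identical(external_confinement(gel, R = 1), 0)
  expect_equal(external_confinement(gel, R = 2), 1.46875, tolerance = 1e-12)
  expect_equal(external_confinement(gel, R = 1e8), 5 / 2, tolerance = 1e-6)
  expect_lt(external_confinement(gel, R = 0.8), 0)  # underfilled cavity pulls
  expect_error(external_confinement(gel, R = -1), "positive")
  expect_identical(external_confinement(confinement("none"), R = 5), 0)
  expect_equal(external_confinement(confinement("hydrostatic", p_bar = 0.4),
                                    R = 5), 0.4)
})

test_that("confinement events switch the active mode at their times", {
  spec <- confinement("gel", c_H = 2, R0 = 10,
                      events = list(list(time = 5, mode = "none"),
                                    list(time = 9, mode = "hydrostatic",
                                         p_bar = 0.3)))
  expect_gt(external_confinement(spec, R = 15, t = 0), 0)
  expect_identical(external_confinement(spec, R = 15, t = 6), 0)
  expect_equal(external_confinement(spec, R = 15, t = 9.5), 0.3)
  expect_error(confinement("gel", c_H = 1, R0 = 1,
                           events = list(list(time = 3), list(time = 2))),
               "increasing")
})

test_that("gel stress field matches the boundary force and far-field limits", {
  for (c_H in c(0.5, 1, 2)) {
    for (ratio in c(1.1, 1.5, 2)) {
      R0 <- 10
      R <- ratio * R0
      spec <- confinement("gel", c_H = c_H, R0 = R0)
      gs <- gel_stress_profile(spec, R, s = R)
      F_ext <- external_confinement(spec, R)
      expect_equal(gs$sigma_rr_tot, -F_ext, tolerance = 1e-6)
    }
  }
  spec <- confinement("gel", c_H = 1, R0 = 10)
  # undeformed gel carries no stress; far field decays to zero
  gs0 <- gel_stress_profile(spec, R = 10, s = c(10, 15, 30))
  expect_equal(gs0$sigma_rr_tot, rep(0, 3), tolerance = 1e-12)
  expect_equal(gs0$sigma_tt_tot, rep(0, 3), tolerance = 1e-12)
  gs <- gel_stress_profile(spec, R = 20, s = c(20, 2e4))
  expect_lt(abs(gs$sigma_rr_tot[2]), 1e-6)
  expect_gt(gs$sigma_tt_tot[1], 0)  # hoop tension at the interface
  expect_error(gel_stress_profile(spec, R = 20, s = 15), "outside")
})

test_that("invariant stress is the weighted total-stress trace", {
  expect_identical(invariant_stress(0, 0), 0)
  expect_identical(invariant_stress(-3, -3), -3)
  expect_identical(invariant_stress(-1, 2), 1)
})

test_that("average elastic energy is the exact volume average", {
  r <- seq(0, 1, length.out = 201)
  s <- elastic_stress(r, r)
  expect_equal(elastic_energy_average(s), 0, tolerance = 1e-12)
  s <- manual_stress(r, rep(1, 201), rep(1, 201))
  s$W <- rep(0.37, 201)
  expect_equal(elastic_energy_average(s), 0.37, tolerance = 1e-12)
  s$W <- r^2
  expect_equal(elastic_energy_average(s), 3 / 5, tolerance = 1e-4)
})

test_that("stress anisotropy vanishes for hydrostatic states and interpolates", {
  r <- seq(0, 1, length.out = 51)
  s <- elastic_stress(r, r)
  expect_equal(stress_anisotropy(s, "boundary"), 0, tolerance = 1e-12)
  expect_equal(stress_anisotropy(s, "center"), 0, tolerance = 1e-12)
  s <- manual_stress(r, rep(0.39685, 51), rep(1.58740, 51))
  expect_equal(stress_anisotropy(s, "boundary"), 1.19055, tolerance = 1e-4)
  expect_equal(stress_anisotropy(s, 0.5), 1.19055, tolerance = 1e-4)
  expect_error(stress_anisotropy(s, 2), "within")
})
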