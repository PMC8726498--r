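#' Quasi-static nutrient profile
#'
#' Concentration of the growth-promoting factor ("nutrient") that diffuses in
#' from the boundary and is taken up at a constant rate by the cells. The
#' quasi-static balance gives the screened-diffusion profile
#' \deqn{c(r) = \frac{R \sinh(r/L)}{r \sinh(R/L)},}
#' with \eqn{c(R) = 1} held fixed (sufficient supply at the boundary) and the
#' center value \eqn{c(0) = R/(L\sinh(R/L))} taken as the \eqn{r \to 0}
#' limit. \eqn{L} is the diffusion (screening) length: growth is confined to
#' a rim of width \eqn{\sim L} when \eqn{R \gg L}. Evaluated with scaled
#' exponentials so large \eqn{R/L} does not overflow.
#'
#' @param grid_r Radial coordinates (first node at 0).
#' @param R Spheroid radius (> 0).
#' @param L Diffusion length (> 0).
#' @return Nutrient concentration per node, in (0, 1] with \code{c(R) = 1}.
#' @export
nutrient_profile <- function(grid_r, R, L) {
  if (R <= 0 || L <= 0) stop("R and L must be positive")
  # sinh(x)/sinh(X) = exp(x - X) * (1 - exp(-2x)) / (1 - exp(-2X))
  x <- grid_r / L
  X <- R / L
  ratio <- exp(x - X) * (1 - exp(-2 * x)) / (1 - exp(-2 * X))
  cc <- numeric(length(grid_r))
  pos <- grid_r > 0
  cc[pos] <- R * ratio[pos] / grid_r[pos]
  cc[!pos] <- (2 * X * exp(-X)) / (1 - exp(-2 * X))  # R/(L sinh(R/L))
  cc[length(cc)] <- 1
  cc
}

#' Mechanochemical rate laws
#'
#' Hill-type responses of water efflux, volume growth, and cell division to
#' the local mechanical state. In all three the indicator gates the feedback:
#' only compressive stress (negative feedback stress) or crowding (density
#' above the reference value 1) engages it.
#'
#' \code{water_efflux_rate}: compression squeezes water out of cells at rate
#' \deqn{\lambda_E = \Delta_A \frac{\gamma_A \sigma^m 1_{\sigma<0}}
#'   {1 + \gamma_A \sigma^m 1_{\sigma<0}},}
#' zero for tensile stress and saturating at \eqn{\Delta_A} under strong
#' compression (\code{m} even keeps \eqn{\sigma^m \ge 0}).
#'
#' \code{growth_rate}: compression inhibits cell volume growth,
#' \deqn{\lambda = \frac{\lambda_0}{1 + \gamma_\lambda \sigma^n
#'   1_{\sigma<0}}.}
#'
#' \code{division_rate}: crowding inhibits division,
#' \deqn{\lambda_c = \frac{\lambda_0}{1 + \gamma_c |\rho_c - 1|^{l}
#'   1_{\rho_c>1}}.}
#'
#' @param sigma Feedback stress per node: the total circumferential stress by
#'   default, or the invariant measure (see
#'   \code{\link{spheroid_params}}, field \code{feedback_stress}).
#' @param rho_c Cell number density per node (reference value 1).
#' @param params A \code{\link{spheroid_params}} object.
#' @return Rate per node (1/time).
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
water_efflux_rate <- function(sigma, params) {
  x <- params$gamma_A * sigma^params$m * (sigma < 0)
  params$Delta_A * x / (1 + x)
}

#' @rdname rate_laws
#' @export
growth_rate <- function(sigma, params) {
  params$lambda0 / (1 + params$gamma_lambda * sigma^params$n * (sigma < 0))
}

#' @rdname rate_laws
#' @export
division_rate <- function(rho_c, params) {
  if (any(rho_c < 0)) stop("cell density must be nonnegative")
  params$lambda0 /
    (1 + params$gamma_c * abs(rho_c - 1)^params$l_hill * (rho_c > 1))
}

#' Radial velocity from the net volumetric rate
#'
#' Incompressibility of the tissue ties the velocity to the net local volume
#' change rate \eqn{\lambda^{net} = \lambda c - \lambda_A}:
#' \deqn{v(r) = \frac{1}{r^2} \int_0^r \lambda^{net}(\eta)\, \eta^2\, d\eta,}
#' evaluated by cumulative product-trapezoid quadrature (piecewise-linear
#' \eqn{\lambda^{net}} against the exact \eqn{\eta^2} weight, which keeps
#' full relative accuracy at the coordinate singularity), with
#' \eqn{v(0) = 0}; the uniform-rate closed form \eqn{v = \lambda^{net} r/3}
#' is recovered exactly. The boundary value \eqn{v(R)} is the growth speed of
#' the spheroid, \eqn{dR/dt = v(R)}.
#'
#' @param lam_net Net volumetric rate per node.
#' @param grid_r Radial coordinates starting at 0.
#' @return Velocity per node.
#' @export
radial_velocity <- function(lam_net, grid_r) {
  n <- length(grid_r)
  a <- grid_r[-n]
  b <- grid_r[-1]
  # cumulative form of integrate_r2(): piecewise-linear lam against the
  # exact eta^2 weight keeps full relative accuracy at the origin
  w_a <- b * (b^3 - a^3) / 3 - (b^4 - a^4) / 4
  w_b <- (b^4 - a^4) / 4 - a * (b^3 - a^3) / 3
  inc <- (lam_net[-n] * w_a + lam_net[-1] * w_b) / (b - a)
  integral <- c(0, cumsum(inc))
  v <- numeric(n)
  v[-1] <- integral[-1] / grid_r[-1]^2
  v    # v(0) = 0 (integrand ~ r^2)
}

#' Evaluate all rate fields for a mechanical state
#'
#' Convenience wrapper used by the simulator: computes the nutrient profile,
#' the feedback stress measure, the three regulated rates, the net volumetric
#' rate \eqn{\lambda^{net} = \lambda c - (\lambda_{A,c} + \lambda_E)}, the
#' net cell proliferation rate
#' \eqn{\lambda_c^{net} = \lambda_c c - \lambda_{A,c}}, and the radial
#' velocity.
#'
#' @param stress A completed \code{stress_profile} (with totals).
#' @param rho_c Cell density per node.
#' @param R Spheroid radius.
#' @param params A \code{\link{spheroid_params}} object.
#' @return A list of per-node fields: \code{c}, \code{sigma_fb}, \code{lam},
#'   \code{lam_E}, \code{lam_A}, \code{lam_c}, \code{lam_net_vol},
#'   \code{lam_net_cell}, \code{v}.
#' @export
rate_fields <- function(stress, rho_c, R, params) {
  r <- stress$grid_r
  cc <- nutrient_profile(r, R, params$L)
  sigma_fb <- if (params$feedback_stress == "invariant") stress$sigma_inv
              else stress$sigma_tt_tot
  lam_E <- water_efflux_rate(sigma_fb, params)
  lam <- growth_rate(sigma_fb, params)
  lam_c <- division_rate(rho_c, params)
  lam_A <- params$lambda_Ac + lam_E
  lam_net_vol <- lam * cc - lam_A
  list(c = cc, sigma_fb = sigma_fb, lam = lam, lam_E = lam_E, lam_A = lam_A,
       lam_c = lam_c, lam_net_vol = lam_net_vol,
       lam_net_cell = lam_c * cc - params$lambda_Ac,
       v = radial_velocity(lam_net_vol, r))
}
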