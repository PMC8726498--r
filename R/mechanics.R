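#' Elastic stresses from the reference map
#'
#' Evaluates the nondimensional deviatoric (elastic) stress components of an
#' incompressible neo-Hookean tissue in spherical symmetry from the reference
#' map \eqn{y(r)}, which gives the reference radial coordinate of the material
#' point currently at radius \eqn{r}:
#' \deqn{\sigma_{rr} = \left(\frac{y/r}{\partial y/\partial r}\right)^{4/3},
#'       \qquad
#'       \sigma_{\theta\theta} =
#'       \left(\frac{\partial y/\partial r}{y/r}\right)^{2/3},}
#' with \eqn{\sigma_{\phi\phi} = \sigma_{\theta\theta}}. Stresses are
#' normalized by the tissue shear modulus. At the center the ratio \eqn{y/r}
#' is replaced by its limit \eqn{\partial y/\partial r(0)}, so a smooth map
#' gives the isotropic unit state there. The radial derivative is computed
#' with second-order central differences (one-sided at the ends).
#'
#' Both components are powers of the positive stretch ratio
#' \eqn{q = (\partial y/\partial r)/(y/r)} and satisfy the algebraic identity
#' \eqn{\sigma_{rr}\,\sigma_{\theta\theta}^2 = 1} at every node.
#'
#' @param y Reference-map values per node; must vanish at the center and be
#'   strictly increasing (tangling of material points is an error).
#' @param grid_r Radial coordinates, ascending and uniformly spaced with the
#'   first node at 0.
#' @return An object of class \code{"stress_profile"}: a list with
#'   \code{grid_r}, \code{sigma_rr}, \code{sigma_tt}, the strain measures
#'   \code{dydr} and \code{y_over_r}, and the elastic energy density \code{W}
#'   (see \code{\link{elastic_energy_average}}). Pressure and total stresses
#'   are filled in by \code{\link{pressure_field}} / \code{\link{total_stress}}.
#' @seealso \code{\link{pressure_field}}, \code{\link{elastic_energy_average}}
#' @export
elastic_stress <- function(y, grid_r) {
  n <- length(grid_r)
  stopifnot(length(y) == n, n >= 3L)
  if (abs(y[1]) > 1e-12 * max(abs(y)))
    stop("invalid deformation: reference map must vanish at the center")
  h <- grid_r[2] - grid_r[1]
  dydr <- fd_gradient(y, h)
  y_over_r <- c(dydr[1], y[-1] / grid_r[-1])
  if (any(dydr <= 0) || any(y_over_r <= 0))
    stop("invalid deformation: reference map is non-monotone (material ",
         "points tangle)")
  q <- dydr / y_over_r
  sigma_rr <- q^(-4 / 3)
  sigma_tt <- q^(2 / 3)
  structure(list(grid_r = grid_r, dydr = dydr, y_over_r = y_over_r,
                 sigma_rr = sigma_rr, sigma_tt = sigma_tt,
                 W = 0.5 * (sigma_rr + 2 * sigma_tt - 3)),
            class = "stress_profile")
}

#' Recover the pressure from radial force balance
#'
#' The tissue is overdamped: the velocity is proportional to the net force,
#' \eqn{\alpha v = -\partial p/\partial r + \partial\sigma_{rr}/\partial r +
#' (2/r)(\sigma_{rr}-\sigma_{\theta\theta})}. Given the elastic stresses and
#' the velocity, the pressure is obtained by integrating this relation inward
#' (trapezoidal rule) from the boundary condition
#' \eqn{p(R) = \sigma_{rr}(R) + F_{ext}}, which enforces the boundary force
#' balance \eqn{\sigma_{rr}^{tot}(R) = -F_{ext}}. The geometric source
#' \eqn{(2/r)(\sigma_{rr}-\sigma_{\theta\theta})} vanishes at \eqn{r = 0} by
#' symmetry.
#'
#' @param stress A \code{stress_profile} from \code{\link{elastic_stress}}.
#' @param v Radial velocity per node, on the same grid.
#' @param alpha Friction coefficient.
#' @param F_ext External confinement force at the boundary (see
#'   \code{\link{external_confinement}}).
#' @return Pressure per node.
#' @export
pressure_field <- function(stress, v, alpha, F_ext = 0) {
  r <- stress$grid_r
  n <- length(r)
  if (length(v) != n) stop("velocity and stress grids do not match")
  h <- r[2] - r[1]
  dsrr <- fd_gradient(stress$sigma_rr, h)
  geom <- c(0, 2 * (stress$sigma_rr[-1] - stress$sigma_tt[-1]) / r[-1])
  dpdr <- -alpha * v + dsrr + geom
  p_R <- stress$sigma_rr[n] + F_ext
  integral <- cumtrapz(r, dpdr)        # from 0 to r
  p_R - (integral[n] - integral)
}

#' Attach pressure and total stresses to a stress profile
#'
#' Completes a \code{stress_profile} with the pressure, the total (Cauchy)
#' stresses \eqn{\sigma^{tot} = \sigma - p}, and the invariant measure
#' \eqn{(2\sigma_{\theta\theta}^{tot} + \sigma_{rr}^{tot})/3}. Compression
#' corresponds to negative total stress.
#'
#' @param stress A \code{stress_profile}.
#' @param p Pressure per node (from \code{\link{pressure_field}}).
#' @return The completed \code{stress_profile}.
#' @export
total_stress <- function(stress, p) {
  stopifnot(length(p) == length(stress$grid_r))
  stress$p <- p
  stress$sigma_rr_tot <- stress$sigma_rr - p
  stress$sigma_tt_tot <- stress$sigma_tt - p
  stress$sigma_inv <- invariant_stress(stress$sigma_rr_tot,
                                       stress$sigma_tt_tot)
  stress
}

#' Invariant measure of the total stress
#'
#' Returns \eqn{(2\sigma_{\theta\theta}^{tot} + \sigma_{rr}^{tot})/3}, the
#' trace-like invariant used as an alternative feedback stress measure.
#'
#' @param sigma_rr_tot,sigma_tt_tot Total radial and circumferential stress.
#' @return The invariant, elementwise.
#' @export
invariant_stress <- function(sigma_rr_tot, sigma_tt_tot) {
  (2 * sigma_tt_tot + sigma_rr_tot) / 3
}

#' External confinement force at the spheroid boundary
#'
#' Evaluates \eqn{F_{ext}} for the active confinement mode at time \code{t}
#' (after applying the event schedule):
#' \itemize{
#'   \item \code{none}: 0 (free growth);
#'   \item \code{gel}: growth into the cavity of an incompressible
#'     neo-Hookean gel of relative shear modulus \eqn{c_H} and reference
#'     cavity radius \eqn{R_0},
#'     \eqn{F_{ext} = \frac{c_H}{2}\left(5 -
#'       \frac{R_0 (R_0^3 + 4R^3)}{R^4}\right)};
#'   \item \code{hydrostatic}: the applied pressure \eqn{\bar p}.
#' }
#' For \eqn{R > R_0} the gel compresses the spheroid (\eqn{F_{ext} > 0}),
#' saturating at \eqn{5 c_H / 2} as \eqn{R/R_0 \to \infty}; for
#' \eqn{R < R_0} the formula is applied as printed and gives
#' \eqn{F_{ext} < 0} (an underfilled cavity pulls on the boundary).
#'
#' @param spec A \code{\link{confinement}} specification.
#' @param R Current spheroid radius (> 0).
#' @param t Time, used to resolve the event schedule.
#' @return Scalar \eqn{F_{ext}} (dimensionless).
#' @export
external_confinement <- function(spec, R, t = 0) {
  if (R <= 0) stop("radius must be positive")
  active <- resolve_confinement(spec, t)
  switch(active$mode,
         none = 0,
         gel = {
           R0 <- active$R0
           (active$c_H / 2) * (5 - R0 * (R0^3 + 4 * R^3) / R^4)
         },
         hydrostatic = active$p_bar)
}

#' Stress field in the confining gel
#'
#' Radial and circumferential total stresses in the incompressible
#' neo-Hookean gel surrounding a spheroid of current radius \eqn{R}, obtained
#' from the cavity-expansion solution. A gel material point currently at
#' radius \eqn{s \ge R} sat at reference radius \eqn{s_0} with
#' \eqn{s^3 - s_0^3 = R^3 - R_0^3} (incompressibility); its principal
#' stretches are \eqn{s/s_0} (circumferential, twice) and \eqn{(s_0/s)^2}
#' (radial). The radial stress follows from integrating the equilibrium
#' relation \eqn{d\sigma_{rr}/ds = (2/s)(\sigma_{\theta\theta}-\sigma_{rr})}
#' inward from zero stress at infinity (adaptive quadrature); the
#' circumferential stress adds the neo-Hookean deviatoric difference
#' \eqn{c_H[(s/s_0)^2 - (s_0/s)^4]}. At \eqn{s = R} the radial stress equals
#' \eqn{-F_{ext}} of \code{\link{external_confinement}}.
#'
#' @param spec A gel-mode \code{\link{confinement}} specification.
#' @param R Current spheroid radius.
#' @param s Query radii, all \code{>= R}.
#' @param t Time (resolves the event schedule).
#' @return A data frame with columns \code{s}, \code{sigma_rr_tot},
#'   \code{sigma_tt_tot}.
#' @export
gel_stress_profile <- function(spec, R, s, t = 0) {
  active <- resolve_confinement(spec, t)
  if (active$mode != "gel") stop("gel_stress_profile requires gel confinement")
  if (any(s < R)) stop("query radii must lie outside the spheroid (s >= R)")
  c_H <- active$c_H
  a <- R^3 - active$R0^3            # cavity volume change (per 4*pi/3)
  dev <- function(x) {              # sigma_tt - sigma_rr at radius x
    s0c <- x^3 - a
    if (any(s0c <= 0)) stop("gel reference radius undefined (s0^3 <= 0)")
    s0 <- s0c^(1 / 3)
    c_H * ((x / s0)^2 - (s0 / x)^4)
  }
  srr <- vapply(s, function(si) {
    -stats::integrate(function(x) 2 * dev(x) / x, si, Inf,
                      rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
  data.frame(s = s, sigma_rr_tot = srr, sigma_tt_tot = srr + dev(s))
}

#' Volume-averaged elastic energy
#'
#' The neo-Hookean energy density is
#' \eqn{W = \tfrac12(\sigma_{rr} + 2\sigma_{\theta\theta} - 3)} (first
#' isochoric invariant minus 3, halved); this returns its volume average
#' \eqn{(3/R^3)\int_0^R W r^2\,dr} over the spheroid. Zero for an unstrained
#' body (\eqn{y \equiv r}).
#'
#' @param stress A \code{stress_profile} defined on \code{[0, R]}.
#' @param R Spheroid radius (defaults to the last grid node).
#' @return Scalar average energy density (units of the shear modulus).
#' @export
elastic_energy_average <- function(stress, R = NULL) {
  r <- stress$grid_r
  if (is.null(R)) R <- r[length(r)]
  (3 / R^3) * integrate_r2(stress$W, r)
}

#' Stress anisotropy
#'
#' The deviatoric stress difference \eqn{\sigma_{\theta\theta} - \sigma_{rr}}
#' (equal for elastic and total stresses, since the pressure cancels),
#' evaluated at a location in \code{[0, R]} by linear interpolation. Exactly
#' zero wherever the stress state is hydrostatic.
#'
#' @param stress A \code{stress_profile}.
#' @param at Location: a radius, or \code{"boundary"} / \code{"center"}.
#' @return Scalar anisotropy (sign retained; positive when the hoop stress
#'   exceeds the radial stress).
#' @export
stress_anisotropy <- function(stress, at = "boundary") {
  r <- stress$grid_r
  aniso <- stress$sigma_tt - stress$sigma_rr
  if (identical(at, "boundary")) return(aniso[length(r)])
  if (identical(at, "center")) return(aniso[1])
  if (!is.numeric(at) || at < r[1] || at > r[length(r)])
    stop("'at' must be 'boundary', 'center', or a radius within [0, R]")
  stats::approx(r, aniso, xout = at)$y
}
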