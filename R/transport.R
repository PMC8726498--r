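#' Tissue state on the moving domain
#'
#' Holds the primary fields of the model at one instant: the boundary radius
#' \code{R}, the reference map \code{y} (reference radial coordinate of the
#' material point currently at \code{r}), and the cell number density
#' \code{rho_c} (reference value 1). Fields live on a fixed scaled
#' coordinate grid \eqn{\xi = r/R \in [0, 1]} so the mesh follows the moving
#' boundary without re-meshing; the physical grid is \code{grid_r = xi * R}.
#'
#' The default initial condition is an unstressed body (\code{y = r}) at
#' uniform density (\code{rho_c = 1}).
#'
#' @param R Initial boundary radius (> 0).
#' @param N Number of grid nodes (>= 8).
#' @param y Optional initial reference map (per node, on \code{xi * R}).
#' @param rho_c Optional initial cell density (per node).
#' @param t Initial time.
#' @return An object of class \code{"tissue_state"}.
#' @examples
#' s <- tissue_state(R = 100, N = 50)
#' head(grid_r(s))
#' @export
tissue_state <- function(R, N = 200L, y = NULL, rho_c = NULL, t = 0) {
  if (R <= 0) stop("R must be positive")
  N <- as.integer(N)
  if (N < 8L) stop("need at least 8 grid nodes")
  xi <- seq(0, 1, length.out = N)
  r <- xi * R
  if (is.null(y)) y <- r
  if (is.null(rho_c)) rho_c <- rep(1, N)
  stopifnot(length(y) == N, length(rho_c) == N)
  if (y[1] != 0) stop("reference map must vanish at the center")
  if (any(diff(y) <= 0)) stop("reference map must be strictly increasing")
  if (any(rho_c < 0)) stop("cell density must be nonnegative")
  structure(list(t = t, R = R, xi = xi, y = y, rho_c = rho_c,
                 v_prev = rep(0, N)),
            class = "tissue_state")
}

#' @rdname tissue_state
#' @param state A \code{tissue_state}.
#' @export
grid_r <- function(state) state$xi * state$R

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("Tissue state at t = %.4g: R = %.6g, %d nodes\n",
              x$t, x$R, length(x$xi)))
  cat(sprintf("  displacement max |r - y| = %.4g, density range [%.4g, %.4g]\n",
              max(abs(grid_r(x) - x$y)), min(x$rho_c), max(x$rho_c)))
  invisible(x)
}

# Upwind one-sided derivative of f for advection velocity w on a uniform
# grid (spacing h): backward difference where w > 0, forward where w < 0.
upwind_gradient <- function(f, w, h) {
  n <- length(f)
  back <- c(0, (f[-1] - f[-n]) / h)       # valid for i >= 2
  fwd <- c((f[-1] - f[-n]) / h, 0)        # valid for i <= n-1
  g <- ifelse(w > 0, back, fwd)
  g[1] <- fwd[1]
  g[n] <- back[n]
  g
}

#' Advance the adaptive reference map
#'
#' One time step of the relaxation–advection law
#' \deqn{\partial_t y + v\, \partial_r y = \beta (r - y),}
#' which lets the reference coordinate adapt to the current coordinate at
#' rate \eqn{\beta}; the displacement \eqn{u = r - y} then decays at rate
#' \eqn{\beta}, relaxing the elastic stress (Maxwell-like). On the scaled
#' grid the advection velocity is the flow relative to the mesh,
#' \eqn{w = v - \xi\, dR/dt}, which vanishes at both the center and the
#' boundary. The scheme splits the step: first-order upwind advection
#' followed by an exact exponential update of the relaxation term, so with
#' \eqn{v \equiv 0} the decay \eqn{u(t) = u_0 e^{-\beta t}} is reproduced to
#' machine precision.
#'
#' @param state A \code{\link{tissue_state}}.
#' @param v Radial velocity per node.
#' @param beta Relaxation rate (>= 0).
#' @param dt Time step; must satisfy the advective CFL bound
#'   \eqn{dt \max|w| \le \Delta r}.
#' @param dRdt Boundary speed; defaults to \code{v} at the boundary.
#' @return The updated reference map (numeric vector).
#' @export
advance_reference_map <- function(state, v, beta, dt, dRdt = v[length(v)]) {
  r <- grid_r(state)
  h <- r[2] - r[1]
  w <- v - state$xi * dRdt
  if (dt <= 0) stop("dt must be positive")
  if (max(abs(w)) * dt > h)
    stop("CFL violation in reference-map advection; reduce dt")
  y <- state$y - dt * w * upwind_gradient(state$y, w, h)
  y <- r + (y - r) * exp(-beta * dt)
  y[1] <- 0
  y
}

#' Advance the cell number density
#'
#' One time step of the cell density balance
#' \deqn{\partial_t \rho_c + v\, \partial_r \rho_c +
#'   \rho_c \frac{1}{r^2}\partial_r(r^2 v) =
#'   \rho_c(\lambda_c c - \lambda_{A,c}) +
#'   \frac{1}{r^2}\partial_r\!\left(D \rho_c r^2 \partial_r \rho_c\right),}
#' where density rises where division outpaces volume gain and is diluted
#' where volume gain dominates; the last term is a density-dependent
#' neighbor-exchange flux with no-flux conditions at the center and the
#' boundary. Incompressibility identifies the dilution factor
#' \eqn{(1/r^2)\partial_r(r^2 v)} with the net volumetric rate, which is
#' used analytically. Advection (relative to the moving mesh) is explicit
#' first-order upwind; the linear-in-density net reaction is integrated
#' exactly over the step (exponential update, so a spatially uniform
#' reaction reproduces the scalar ODE solution and positivity is
#' preserved); diffusion is implicit (backward Euler)
#' with the \eqn{\rho_c}-dependent coefficient lagged one step, discretized
#' in conservative finite-volume form so the discrete cell number
#' (\code{\link{total_cell_number}}) is conserved exactly when reactions and
#' boundary motion vanish.
#'
#' @param state A \code{\link{tissue_state}}.
#' @param v Radial velocity per node.
#' @param rates Rate fields from \code{\link{rate_fields}} (uses
#'   \code{lam_net_cell} and \code{lam_net_vol}).
#' @param D Cell mobility.
#' @param dt Time step (advective CFL bound applies).
#' @param dRdt Boundary speed; defaults to \code{v} at the boundary.
#' @return The updated cell density (numeric vector).
#' @export
advance_cell_density <- function(state, v, rates, D, dt,
                                 dRdt = v[length(v)]) {
  r <- grid_r(state)
  n <- length(r)
  h <- r[2] - r[1]
  w <- v - state$xi * dRdt
  if (dt <= 0) stop("dt must be positive")
  if (max(abs(w)) * dt > h)
    stop("CFL violation in cell-density advection; reduce dt")
  rho <- state$rho_c
  # advect (explicit upwind), then integrate the linear-in-rho net reaction
  # exactly over the step (exponential update; positivity preserving)
  rho_star <- (rho - dt * w * upwind_gradient(rho, w, h)) *
    exp(dt * (rates$lam_net_cell - rates$lam_net_vol))
  if (D > 0) {
    # conservative FV diffusion, implicit in rho with lagged coefficient
    r_face <- (r[-1] + r[-n]) / 2
    rho_face <- (rho[-1] + rho[-n]) / 2
    Fface <- D * rho_face * r_face^2 / h          # n-1 face conductances
    V <- shell_volumes(r)
    lower <- -dt * Fface / V[-1]
    upper <- -dt * Fface / V[-n]
    diag <- 1 + dt * (c(Fface, 0) + c(0, Fface)) / V
    rho_new <- solve_tridiag(lower, diag, upper, rho_star)
  } else {
    rho_new <- rho_star
  }
  if (any(rho_new < 0))
    stop("cell density went negative; reduce dt (stability error)")
  rho_new
}

# Exact spherical shell volumes (per 4*pi/3... actually per 4*pi) around each
# node of a uniform radial grid; cell edges at midpoints, clipped to [0, R].
shell_volumes <- function(r) {
  n <- length(r)
  h <- r[2] - r[1]
  lo <- pmax(r - h / 2, 0)
  hi <- pmin(r + h / 2, r[n])
  (hi^3 - lo^3) / 3
}

#' Discrete total cell number
#'
#' The quadrature \eqn{\int_0^R \rho_c r^2 \, dr} evaluated with the same
#' shell volumes used by the conservative diffusion scheme, so it is the
#' exactly conserved discrete invariant under pure no-flux diffusion.
#'
#' @param state A \code{\link{tissue_state}}.
#' @return Scalar cell number (up to the factor \eqn{4\pi}).
#' @export
total_cell_number <- function(state) {
  sum(shell_volumes(grid_r(state)) * state$rho_c)
}

#' Re-express the state on a rescaled grid
#'
#' Interpolates the reference map and cell density onto the scaled grid of a
#' new boundary radius, using monotone cubic interpolation (exact on linear
#' fields, monotonicity preserving, so the state invariants survive). Points
#' of the new grid beyond the old domain (growth) are extrapolated by the
#' end cubic.
#'
#' @param state A \code{\link{tissue_state}}.
#' @param new_R New boundary radius (> 0).
#' @return A \code{tissue_state} with radius \code{new_R}.
#' @export
regrid <- function(state, new_R) {
  if (new_R <= 0) stop("new_R must be positive")
  if (new_R == state$R) return(state)
  r_old <- grid_r(state)
  r_new <- state$xi * new_R
  fy <- stats::splinefun(r_old, state$y, method = "hyman")
  frho <- stats::splinefun(r_old, state$rho_c, method = "monoH.FC")
  y <- fy(r_new)
  y[1] <- 0
  rho <- pmax(frho(r_new), 0)
  out <- state
  out$R <- new_R
  out$y <- y
  out$rho_c <- rho
  out
}
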