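# Coupled time stepper: nutrient -> mechanics -> rates -> transport -> moving
# boundary. Operator splitting is first-order; the boundary radius itself is
# advanced with a Heun (predictor-corrector) update because the radius series
# is the primary observable.

# Evaluate the full mechanical/kinetic state of the tissue at its current
# configuration. The friction term in the force balance couples pressure and
# velocity; with drag alpha << 1 the coupling is weak and two Picard sweeps
# (seeded by the previous step's velocity) converge it far below the
# discretization error.
evaluate_state <- function(state, params, conf) {
  r <- grid_r(state)
  stress_el <- elastic_stress(state$y, r)
  F_ext <- external_confinement(conf, state$R, state$t)
  v_it <- state$v_prev
  stress <- NULL
  rates <- NULL
  for (k in 1:2) {
    p <- pressure_field(stress_el, v_it, params$alpha, F_ext)
    stress <- total_stress(stress_el, p)
    rates <- rate_fields(stress, state$rho_c, state$R, params)
    v_it <- rates$v
  }
  list(stress = stress, rates = rates, F_ext = F_ext)
}

#' One time step of the coupled model
#'
#' Advances the tissue state by \code{dt} with the splitting
#' (1) nutrient profile, (2) elastic stress and pressure recovery under the
#' active confinement, (3) mechanochemically regulated rates and the radial
#' velocity, (4) upwind transport of the reference map and cell density on
#' the moving scaled grid, and (5) boundary motion \eqn{dR/dt = v(R)} with a
#' Heun corrector (the corrector re-evaluates the mechanics at the predicted
#' state). On the scaled grid the re-expression of fields after boundary
#' motion is the identity, so no interpolation is needed within a step.
#'
#' @param state A \code{\link{tissue_state}}.
#' @param params A \code{\link{spheroid_params}}.
#' @param conf A \code{\link{confinement}} specification.
#' @param dt Time step; advective CFL violations are errors.
#' @return The advanced \code{tissue_state}.
#' @seealso \code{\link{run_spheroid}} for full trajectories.
#' @export
step_spheroid <- function(state, params, conf, dt) {
  ev <- evaluate_state(state, params, conf)
  advance_state(state, ev, params, conf, dt)$state
}

# Core advance shared by step_spheroid and run_spheroid; `ev` is the
# evaluation at `state`. Returns the new state plus the corrector evaluation
# (valid at the predicted radius, reused for diagnostics).
advance_state <- function(state, ev, params, conf, dt) {
  v <- ev$rates$v
  n <- length(v)
  vR0 <- v[n]
  y_new <- advance_reference_map(state, v, params$beta, dt, dRdt = vR0)
  rho_new <- advance_cell_density(state, v, ev$rates, params$D, dt,
                                  dRdt = vR0)
  pred <- state
  pred$t <- state$t + dt
  pred$R <- state$R + dt * vR0
  pred$y <- y_new
  pred$rho_c <- rho_new
  pred$v_prev <- v
  ev1 <- evaluate_state(pred, params, conf)
  vR1 <- ev1$rates$v[n]
  pred$R <- state$R + dt * (vR0 + vR1) / 2
  pred$v_prev <- ev1$rates$v
  list(state = pred, ev_pred = ev1)
}

# Scalar diagnostics of one evaluated state.
state_diagnostics <- function(state, ev) {
  r <- grid_r(state)
  h <- r[2] - r[1]
  stress <- ev$stress
  dstt <- fd_gradient(stress$sigma_tt_tot, h)
  imax <- which.max(state$rho_c)
  list(R = state$R,
       avg_density = (3 / state$R^3) * integrate_r2(state$rho_c, r),
       avg_energy = elastic_energy_average(stress, state$R),
       anisotropy_boundary = stress_anisotropy(stress, "boundary"),
       avg_stress_gradient = trapz(r, abs(dstt)) / state$R,
       sigma_tt_tot_center = stress$sigma_tt_tot[1],
       sigma_tt_tot_boundary = stress$sigma_tt_tot[length(r)],
       argmax_rho_frac = state$xi[imax],
       F_ext = ev$F_ext)
}

# Full per-node snapshot table.
state_snapshot <- function(state, ev) {
  r <- grid_r(state)
  st <- ev$stress
  ra <- ev$rates
  data.frame(t = state$t, r = r, y = state$y, rho_c = state$rho_c,
             c = ra$c, v = ra$v,
             sigma_rr = st$sigma_rr, sigma_tt = st$sigma_tt, p = st$p,
             sigma_rr_tot = st$sigma_rr_tot, sigma_tt_tot = st$sigma_tt_tot,
             sigma_inv = st$sigma_inv, W = st$W,
             lam = ra$lam, lam_E = ra$lam_E, lam_c = ra$lam_c,
             lam_net = ra$lam_net_vol)
}

#' Divergence consistency of the velocity field
#'
#' Incompressibility requires \eqn{(1/r^2)\partial_r(r^2 v) = \lambda^{net}}
#' pointwise. The velocity is constructed by quadrature of exactly this
#' relation, so differencing it back should recover \eqn{\lambda^{net}} to
#' discretization accuracy; the returned maximum absolute residual is a
#' cheap audit of the spatial scheme.
#'
#' @param snapshot A per-node snapshot data frame (from a simulation result).
#' @return Max absolute residual over the nodes.
#' @export
audit_incompressibility <- function(snapshot) {
  r <- snapshot$r
  h <- r[2] - r[1]
  # expanded form v' + 2v/r: differencing r^2 v directly loses relative
  # accuracy next to the coordinate singularity (r^2 v ~ r^3 there)
  dv <- fd_gradient(snapshot$v, h)
  div <- dv + c(2 * dv[1], 2 * snapshot$v[-1] / r[-1])
  max(abs(div - snapshot$lam_net))
}

#' Run a spheroid growth simulation
#'
#' Integrates the coupled model from an initial (by default unstressed,
#' uniform-density) state, applying confinement events at their scheduled
#' times, and optionally stopping once the radius is steady. The time step
#' is adaptive: \code{CFL} times the advective limit of the mesh-relative
#' velocity, capped at \code{0.1 / max(beta, lambda0)} so the relaxation and
#' growth scales stay resolved, and trimmed to land exactly on event and
#' snapshot times. The forward model contains no randomness: results are
#' reproducible bitwise for fixed inputs.
#'
#' @param params A \code{\link{spheroid_params}}.
#' @param conf A \code{\link{confinement}} specification (default: free).
#' @param t_end Final time (ignored if \code{until_steady} reaches
#'   equilibrium first).
#' @param R0 Initial radius (used if \code{state} is NULL).
#' @param N Number of grid nodes.
#' @param state Optional initial \code{\link{tissue_state}}.
#' @param snapshot_times Times at which to store full per-node snapshots and
#'   scalar diagnostics; defaults to 21 evenly spaced times. The initial and
#'   final states are always included.
#' @param until_steady If TRUE, stop as soon as
#'   \code{\link{detect_steady_state}} reports equilibrium (checked
#'   periodically), running at most to \code{t_end}.
#' @param steady_tol,steady_window Steadiness criterion forwarded to
#'   \code{\link{detect_steady_state}}.
#' @param CFL Advective Courant number (0 < CFL <= 1).
#' @param dt_max Optional explicit cap on the time step (e.g. for temporal
#'   convergence studies); the relaxation/growth cap still applies.
#' @return An object of class \code{"spheroid_result"}: a list with the
#'   per-step \code{times} and \code{radius} series, a \code{series} data
#'   frame of scalar diagnostics at snapshot times, a list of per-node
#'   \code{snapshots}, the final \code{state}, and the inputs.
#' @examples
#' \donttest{
#' res <- run_spheroid(spheroid_params(L = 20), t_end = 5, R0 = 20, N = 60)
#' tail(res$radius, 1)
#' }
#' @export
run_spheroid <- function(params, conf = confinement("none"), t_end,
                         R0 = 100, N = 200L, state = NULL,
                         snapshot_times = NULL, until_steady = FALSE,
                         steady_tol = 1e-4, steady_window = 20, CFL = 0.4,
                         dt_max = NULL) {
  stopifnot(inherits(params, "spheroid_params"),
            inherits(conf, "confinement_spec"), t_end > 0,
            CFL > 0, CFL <= 1)
  if (is.null(state)) state <- tissue_state(R = R0, N = N)
  if (is.null(snapshot_times))
    snapshot_times <- seq(state$t, t_end, length.out = 21L)
  snapshot_times <- sort(unique(c(snapshot_times, t_end)))
  event_times <- vapply(conf$events, function(e) as.numeric(e$time),
                        numeric(1))
  # a run with scheduled events may not be declared steady before the last
  # event has fired and a full assessment window has elapsed after it
  min_stop <- if (length(event_times)) max(event_times) + steady_window
              else -Inf
  dt_cap <- min(0.1 / max(params$beta, params$lambda0), dt_max %||% Inf)

  times <- state$t
  radius <- state$R
  snapshots <- list()
  series <- list()
  last_check <- state$t

  take_snapshot <- function(state, ev) {
    snapshots[[length(snapshots) + 1L]] <<- state_snapshot(state, ev)
    series[[length(series) + 1L]] <<-
      c(t = state$t, unlist(state_diagnostics(state, ev)))
  }

  ev <- evaluate_state(state, params, conf)
  take_snapshot(state, ev)
  pending <- snapshot_times[snapshot_times > state$t + 1e-12]

  while (state$t < t_end - 1e-12) {
    h <- state$R * (state$xi[2] - state$xi[1])
    w <- ev$rates$v - state$xi * ev$rates$v[length(state$xi)]
    dt <- min(dt_cap, if (max(abs(w)) > 0) CFL * h / max(abs(w)) else Inf)
    # land exactly on events, snapshots and the horizon
    barriers <- c(t_end, pending[1], event_times[event_times > state$t + 1e-12][1])
    dt <- min(dt, min(barriers, na.rm = TRUE) - state$t)
    if (dt <= 1e-12) stop("time step collapsed below floor at t = ", state$t)

    adv <- advance_state(state, ev, params, conf, dt)
    state <- adv$state
    # the corrector evaluation was made at the predicted radius, which
    # differs from the corrected one by O(dt^2); refresh it for accuracy of
    # diagnostics and of the next step's CFL estimate
    ev <- evaluate_state(state, params, conf)
    times <- c(times, state$t)
    radius <- c(radius, state$R)

    if (length(pending) && state$t >= pending[1] - 1e-9) {
      take_snapshot(state, ev)
      pending <- pending[pending > state$t + 1e-12]
    }
    if (until_steady && state$t >= min_stop &&
        state$t - last_check >= steady_window / 4) {
      last_check <- state$t
      ss <- detect_steady_state(list(times = times, radius = radius),
                                tol = steady_tol, window = steady_window)
      if (ss$is_steady) break
    }
  }
  if (abs(times[length(times)] - series[[length(series)]]["t"]) > 1e-9)
    take_snapshot(state, ev)

  structure(list(times = times, radius = radius,
                 series = as.data.frame(do.call(rbind, series)),
                 snapshots = snapshots, state = state,
                 params = params, conf = conf),
            class = "spheroid_result")
}

#' @export
print.spheroid_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Spheroid growth run: t in [%.4g, %.4g], %d steps\n",
              x$times[1], x$times[n], n - 1L))
  cat(sprintf("  radius %.6g -> %.6g; %d snapshots\n",
              x$radius[1], x$radius[n], length(x$snapshots)))
  ss <- detect_steady_state(x)
  if (ss$is_steady)
    cat(sprintf("  steady at R_inf = %.6g (t_eq = %.4g)\n", ss$R_inf, ss$t_eq))
  invisible(x)
}

#' @export
plot.spheroid_result <- function(x, ...) {
  graphics::plot(x$times, x$radius, type = "l", xlab = "time (days)",
                 ylab = "spheroid radius (micron)", ...)
  invisible(x)
}

#' Detect a steady-state radius
#'
#' The trajectory is steady when \eqn{|dR/dt| < tol \cdot R} everywhere in
#' the trailing time window. Also reports the equilibrium radius (trailing
#' mean) and the earliest time from which the criterion holds over a full
#' window.
#'
#' @param result A \code{spheroid_result}, or any list with \code{times} and
#'   \code{radius}.
#' @param tol Relative rate tolerance (per unit time).
#' @param window Width of the assessment window (time units).
#' @return A list \code{(is_steady, R_inf, t_eq)}; \code{t_eq} is \code{NA}
#'   when the trajectory never satisfies the criterion.
#' @export
detect_steady_state <- function(result, tol = 1e-4, window = 20) {
  t <- result$times
  R <- result$radius
  n <- length(t)
  if (n < 3L || t[n] - t[1] < window)
    return(list(is_steady = FALSE, R_inf = NA_real_, t_eq = NA_real_))
  dRdt <- diff(R) / diff(t)
  Rmid <- (R[-1] + R[-n]) / 2
  tmid <- (t[-1] + t[-n]) / 2
  ok <- abs(dRdt) < tol * Rmid
  steady_through <- function(t_hi) {
    sel <- tmid >= t_hi - window & tmid <= t_hi
    length(sel) && any(sel) && all(ok[sel])
  }
  is_steady <- steady_through(t[n])
  # earliest time with a clean trailing window
  t_eq <- NA_real_
  cand <- t[t >= t[1] + window]
  for (tc in cand) {
    if (steady_through(tc)) { t_eq <- tc; break }
  }
  R_inf <- if (is_steady) mean(R[t >= t[n] - window]) else NA_real_
  list(is_steady = is_steady, R_inf = R_inf, t_eq = t_eq)
}

#' Residual of the equilibrium boundary-strain relation
#'
#' At the equilibrium radius the boundary velocity vanishes and the
#' relaxation law pins the boundary strain of the reference map:
#' \deqn{\partial_r y(R_\infty) =
#'   \frac{\beta}{\beta + \lambda(R_\infty) - \lambda_A(R_\infty)}.}
#' With no relaxation (\eqn{\beta = 0}) the strain collapses to zero — a
#' singular elastic state — while \eqn{\beta \gg \lambda_0} restores
#' \eqn{y \approx r}. This returns the absolute difference between the
#' measured boundary strain and the relation evaluated with the equilibrium
#' rate fields; a small residual certifies the run has truly equilibrated.
#'
#' @param state A \code{\link{tissue_state}} at equilibrium (e.g.
#'   \code{result$state} after \code{until_steady}).
#' @param params The parameters of the run.
#' @param conf The confinement of the run (default free).
#' @return Absolute residual of the relation.
#' @export
check_boundary_strain_relation <- function(state, params,
                                           conf = confinement("none")) {
  ev <- evaluate_state(state, params, conf)
  n <- length(state$xi)
  dydr_R <- ev$stress$dydr[n]
  lam_net_R <- ev$rates$lam_net_vol[n]
  abs(dydr_R - params$beta / (params$beta + lam_net_R))
}

#' Parametric sweep over relaxation rate and gel stiffness
#'
#' Runs the model to steady state on a grid of relaxation rates \code{beta}
#' and relative gel moduli \code{c_H} (gel cavity reference radius =
#' initial radius, so confinement engages as the spheroid grows) and
#' tabulates the equilibrium diagnostics: steady radius, volume-averaged
#' elastic energy and cell density, boundary stress anisotropy, mean
#' absolute radial gradient of the total hoop stress, center hoop stress,
#' the radial location of the density maximum (as a fraction of the
#' radius), and whether the radius dynamics were non-monotone (an interior
#' extremum of \eqn{R(t)} deviating more than 1\% of \eqn{R_\infty}).
#'
#' @param params Base parameters; \code{beta} is overridden per cell.
#' @param beta_grid,cH_grid Grid values (nonempty).
#' @param R0 Initial spheroid radius and gel cavity reference radius.
#' @param N Grid nodes per run.
#' @param t_max Time horizon per run.
#' @param steady_tol,steady_window Steadiness criterion.
#' @return A long-format data frame keyed by \code{(beta, c_H)}; runs that
#'   fail are kept as rows with \code{converged = FALSE} and NA diagnostics.
#' @export
sweep_beta_cH <- function(params, beta_grid = c(0.4, 0.8, 1.2, 1.6),
                          cH_grid = c(0, 0.25, 0.5, 0.75),
                          R0 = 100, N = 100L, t_max = 400,
                          steady_tol = 1e-4, steady_window = 20) {
  stopifnot(length(beta_grid) > 0, length(cH_grid) > 0)
  rows <- list()
  for (b in beta_grid) {
    for (ch in cH_grid) {
      p <- update_params(params, beta = b)
      conf <- if (ch > 0) confinement("gel", c_H = ch, R0 = R0)
              else confinement("none")
      row <- tryCatch({
        res <- run_spheroid(p, conf, t_end = t_max, R0 = R0, N = N,
                            until_steady = TRUE, steady_tol = steady_tol,
                            steady_window = steady_window)
        ss <- detect_steady_state(res, tol = steady_tol,
                                  window = steady_window)
        d <- as.list(res$series[nrow(res$series), ])
        R_inf <- if (ss$is_steady) ss$R_inf else res$radius[length(res$radius)]
        data.frame(beta = b, c_H = ch, converged = ss$is_steady,
                   R_inf = R_inf,
                   avg_energy = d$avg_energy,
                   anisotropy_boundary = d$anisotropy_boundary,
                   avg_stress_gradient = d$avg_stress_gradient,
                   avg_density = d$avg_density,
                   argmax_rho_frac = d$argmax_rho_frac,
                   sigma_tt_tot_center = d$sigma_tt_tot_center,
                   non_monotone = is_non_monotone(res$radius, R_inf))
      }, error = function(e) {
        data.frame(beta = b, c_H = ch, converged = FALSE, R_inf = NA_real_,
                   avg_energy = NA_real_, anisotropy_boundary = NA_real_,
                   avg_stress_gradient = NA_real_, avg_density = NA_real_,
                   argmax_rho_frac = NA_real_,
                   sigma_tt_tot_center = NA_real_, non_monotone = NA)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# TRUE when R(t) has an interior extremum deviating > 1% of R_inf from the
# enclosing endpoint values (robust to discretization wiggle).
is_non_monotone <- function(R, R_inf) {
  n <- length(R)
  if (n < 3L) return(FALSE)
  tol <- 0.01 * R_inf
  overshoot <- max(R) - max(R[1], R[n])
  undershoot <- min(R[1], R[n]) - min(R)
  i_max <- which.max(R)
  i_min <- which.min(R)
  (overshoot > tol && i_max > 1L && i_max < n) ||
    (undershoot > tol && i_min > 1L && i_min < n)
}
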