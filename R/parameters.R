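#' Model parameters for the spheroid growth model
#'
#' Constructs and validates the full set of dimensionless rate, feedback and
#' transport constants of the continuum model. Time is measured in units of
#' the characteristic cell-cycle time (1 day) and length in units of 1 micron;
#' stresses are normalized by the shear modulus of the tumor tissue.
#'
#' The default values are calibration-free placeholders chosen to reproduce
#' the qualitative regimes of confined spheroid growth (nutrient-limited rim
#' growth, compression-induced water efflux, crowding-limited division); they
#' are not fitted to any experimental data set.
#'
#' @param lambda0 Base rate of cell volume growth and of cell division
#'   (1/time). Must be positive.
#' @param lambda_Ac Apoptosis rate (1/time), contributing to both volume loss
#'   and cell number loss.
#' @param Delta_A Maximum rate of compression-induced water efflux (1/time).
#' @param gamma_A Feedback strength of compressive stress on water efflux
#'   (dimensionless Hill prefactor).
#' @param gamma_lambda Feedback strength of compressive stress on volume
#'   growth.
#' @param gamma_c Feedback strength of crowding (cell density above the
#'   reference value 1) on the division rate.
#' @param m,n Positive even integer Hill exponents for the stress feedback on
#'   water efflux (\code{m}) and on volume growth (\code{n}). Evenness makes
#'   the stress powers nonnegative so the Hill forms saturate monotonically.
#' @param l_hill Positive integer Hill coefficient for the density feedback on
#'   division.
#' @param L Nutrient diffusion (screening) length; small \code{L} confines
#'   growth to the spheroid rim.
#' @param D Cell-density mobility (length^2/time) of the neighbor-exchange
#'   flux.
#' @param alpha Friction (drag) coefficient linking velocity to the net force.
#' @param beta Stress-relaxation rate (1/time): how fast the reference map
#'   adapts to the current configuration. \code{beta = 0} disables relaxation.
#' @param feedback_stress Which stress measure enters the efflux and growth
#'   feedbacks: the total circumferential stress \code{"sigma_tt_tot"}
#'   (default; it represents two principal directions) or the trace-like
#'   \code{"invariant"} (2 sigma_tt_tot + sigma_rr_tot)/3.
#' @param tau_scale,length_scale Nondimensionalization metadata (days,
#'   microns); informational only.
#'
#' @return An object of class \code{"spheroid_params"} (a validated list).
#' @examples
#' p <- spheroid_params(beta = 0.4)
#' p$lambda0
#' @export
spheroid_params <- function(lambda0 = 1, lambda_Ac = 0.3, Delta_A = 0.5,
                            gamma_A = 1, gamma_lambda = 0, gamma_c = 1,
                            m = 2L, n = 2L, l_hill = 2L,
                            L = 50, D = 1, alpha = 1e-3, beta = 0.4,
                            feedback_stress = c("sigma_tt_tot", "invariant"),
                            tau_scale = 1, length_scale = 1) {
  feedback_stress <- match.arg(feedback_stress)
  p <- list(lambda0 = lambda0, lambda_Ac = lambda_Ac, Delta_A = Delta_A,
            gamma_A = gamma_A, gamma_lambda = gamma_lambda, gamma_c = gamma_c,
            m = as.integer(m), n = as.integer(n), l_hill = as.integer(l_hill),
            L = L, D = D, alpha = alpha, beta = beta,
            feedback_stress = feedback_stress,
            tau_scale = tau_scale, length_scale = length_scale)
  validate_spheroid_params(p)
  structure(p, class = "spheroid_params")
}

validate_spheroid_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (key in c("lambda0", "lambda_Ac", "Delta_A", "gamma_A", "gamma_lambda",
                "gamma_c", "L", "D", "alpha", "beta")) {
    if (!num1(p[[key]])) stop("parameter '", key, "' must be a finite number")
  }
  if (p$lambda0 <= 0) stop("parameter 'lambda0' must be > 0")
  if (p$L <= 0) stop("parameter 'L' must be > 0")
  for (key in c("lambda_Ac", "Delta_A", "gamma_A", "gamma_lambda", "gamma_c",
                "D", "alpha", "beta")) {
    if (p[[key]] < 0) stop("parameter '", key, "' must be >= 0")
  }
  for (key in c("m", "n")) {
    v <- p[[key]]
    if (!num1(v) || v < 2 || v %% 2 != 0)
      stop("parameter '", key, "' must be a positive even integer >= 2")
  }
  if (!num1(p$l_hill) || p$l_hill < 1 || p$l_hill %% 1 != 0)
    stop("parameter 'l_hill' must be a positive integer")
  if (!p$feedback_stress %in% c("sigma_tt_tot", "invariant"))
    stop("parameter 'feedback_stress' must be 'sigma_tt_tot' or 'invariant'")
  invisible(p)
}

#' @export
print.spheroid_params <- function(x, ...) {
  cat("Spheroid growth model parameters (dimensionless):\n")
  num <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[num])
  cat(paste0("  ", format(names(vals), width = 13), " = ", format(vals)),
      sep = "\n")
  cat("  feedback stress measure:", x$feedback_stress, "\n")
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced and the
#' result re-validated.
#'
#' @param params A \code{spheroid_params} object.
#' @param ... Named replacement values, e.g. \code{beta = 1}.
#' @return A new \code{spheroid_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "spheroid_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  p$m <- as.integer(p$m); p$n <- as.integer(p$n)
  p$l_hill <- as.integer(p$l_hill)
  validate_spheroid_params(p)
  structure(p, class = "spheroid_params")
}

#' External confinement specification
#'
#' Describes the mechanical loading applied at the spheroid boundary: nothing
#' (free growth), an incompressible neo-Hookean gel into whose cavity the
#' spheroid grows, or an applied hydrostatic pressure. A schedule of timed
#' events can switch the loading mid-run (e.g. gel removal or pressure
#' release).
#'
#' @param mode One of \code{"none"}, \code{"gel"}, \code{"hydrostatic"}.
#' @param c_H Shear modulus of the gel relative to the tumor tissue
#'   (dimensionless, >= 0). Required for \code{mode = "gel"}.
#' @param R0 Reference (undeformed) radius of the gel cavity (> 0). Required
#'   for \code{mode = "gel"}.
#' @param p_bar Applied hydrostatic pressure (dimensionless, >= 0). Required
#'   for \code{mode = "hydrostatic"}.
#' @param events Optional list of events, each itself a list with a \code{time}
#'   field plus the new \code{mode} and its parameters, e.g.
#'   \code{list(list(time = 17, mode = "none"))} for gel removal at t = 17.
#'   Event times must be strictly increasing.
#' @return An object of class \code{"confinement_spec"}.
#' @examples
#' free <- confinement("none")
#' gel  <- confinement("gel", c_H = 1.8, R0 = 100)
#' release <- confinement("gel", c_H = 1.8, R0 = 100,
#'                        events = list(list(time = 17, mode = "none")))
#' @export
confinement <- function(mode = c("none", "gel", "hydrostatic"),
                        c_H = NULL, R0 = NULL, p_bar = NULL,
                        events = list()) {
  mode <- match.arg(mode)
  spec <- list(mode = mode, c_H = c_H, R0 = R0, p_bar = p_bar,
               events = events)
  validate_confinement(spec)
  structure(spec, class = "confinement_spec")
}

validate_confinement <- function(spec) {
  check_mode <- function(mode, c_H, R0, p_bar) {
    if (mode == "gel") {
      if (is.null(c_H) || c_H < 0) stop("gel confinement requires c_H >= 0")
      if (is.null(R0) || R0 <= 0) stop("gel confinement requires R0 > 0")
    } else if (mode == "hydrostatic") {
      if (is.null(p_bar) || p_bar < 0)
        stop("hydrostatic confinement requires p_bar >= 0")
    }
  }
  check_mode(spec$mode, spec$c_H, spec$R0, spec$p_bar)
  if (length(spec$events)) {
    times <- vapply(spec$events, function(e) as.numeric(e$time), numeric(1))
    if (any(!is.finite(times)) || any(diff(times) <= 0))
      stop("confinement event times must be finite and strictly increasing")
    for (e in spec$events) {
      mode <- if (is.null(e$mode)) spec$mode else e$mode
      if (!mode %in% c("none", "gel", "hydrostatic"))
        stop("unknown confinement event mode: ", mode)
      check_mode(mode,
                 if (is.null(e$c_H)) spec$c_H else e$c_H,
                 if (is.null(e$R0)) spec$R0 else e$R0,
                 if (is.null(e$p_bar)) spec$p_bar else e$p_bar)
    }
  }
  invisible(spec)
}

#' Resolve the active confinement at a given time
#'
#' Applies the event schedule: the last event with \code{time <= t} (if any)
#' overrides the base mode and parameters.
#'
#' @param spec A \code{confinement_spec}.
#' @param t Time at which to resolve.
#' @return A \code{confinement_spec} with an empty event list.
#' @export
resolve_confinement <- function(spec, t) {
  stopifnot(inherits(spec, "confinement_spec"))
  mode <- spec$mode; c_H <- spec$c_H; R0 <- spec$R0; p_bar <- spec$p_bar
  for (e in spec$events) {
    if (e$time <= t) {
      if (!is.null(e$mode)) mode <- e$mode
      if (!is.null(e$c_H)) c_H <- e$c_H
      if (!is.null(e$R0)) R0 <- e$R0
      if (!is.null(e$p_bar)) p_bar <- e$p_bar
    }
  }
  confinement(mode, c_H = c_H, R0 = R0, p_bar = p_bar)
}

#' @export
print.confinement_spec <- function(x, ...) {
  cat("Confinement:", x$mode)
  if (x$mode == "gel") cat(sprintf(" (c_H = %g, cavity R0 = %g)", x$c_H, x$R0))
  if (x$mode == "hydrostatic") cat(sprintf(" (p_bar = %g)", x$p_bar))
  cat("\n")
  for (e in x$events) {
    cat(sprintf("  event at t = %g: switch to %s\n", e$time,
                if (is.null(e$mode)) x$mode else e$mode))
  }
  invisible(x)
}
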