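# Grid-search calibration of the growth model against radius time series and
# relative-density summaries, with corrected-AIC comparison of model
# variants, plus a synthetic-observation generator for recovery studies.
# All conditions of an observation set share the tumor-associated
# parameters; only the confinement (c_H or p_bar) differs per condition.

#' Observation set for calibration
#'
#' Bundles timestamped spheroid radius measurements and relative-density
#' summaries across experimental conditions (e.g. free suspension and one or
#' more gel concentrations), each condition described by a
#' \code{\link{confinement}} specification.
#'
#' @param radius_obs Data frame with columns \code{condition}, \code{time},
#'   \code{radius}, \code{sd} (measurement noise; used to normalize
#'   residuals).
#' @param density_obs Data frame (possibly empty) with columns
#'   \code{condition}, \code{kind} (\code{"average_ratio_vs_free"} or
#'   \code{"center_ratio_vs_free"}), \code{value}, \code{sd}. Values are
#'   densities of the compressed tumor relative to the free tumor at the
#'   final observation time.
#' @param conditions Named list of \code{confinement_spec}s, one per
#'   condition id; must contain \code{"free"} when density ratios are
#'   present.
#' @param provenance List describing the origin (\code{synthetic} with seed
#'   and true parameters, or \code{user}).
#' @return An object of class \code{"observation_set"}.
#' @export
observation_set <- function(radius_obs, density_obs = NULL, conditions,
                            provenance = list(source = "user")) {
  need <- c("condition", "time", "radius", "sd")
  if (!all(need %in% names(radius_obs)))
    stop("radius_obs needs columns: ", paste(need, collapse = ", "))
  if (any(radius_obs$radius <= 0)) stop("radii must be positive")
  if (any(radius_obs$time < 0)) stop("observation times must be >= 0")
  if (is.null(density_obs))
    density_obs <- data.frame(condition = character(), kind = character(),
                              value = numeric(), sd = numeric())
  missing_conds <- setdiff(unique(c(radius_obs$condition,
                                    density_obs$condition)),
                           names(conditions))
  if (length(missing_conds))
    stop("no confinement spec for condition(s): ",
         paste(missing_conds, collapse = ", "))
  if (nrow(density_obs) && !"free" %in% names(conditions))
    stop("density ratios require a 'free' condition")
  structure(list(radius_obs = radius_obs, density_obs = density_obs,
                 conditions = conditions, provenance = provenance),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d radius points, %d density summaries, %d conditions (%s)\n",
              nrow(x$radius_obs), nrow(x$density_obs),
              length(x$conditions), paste(names(x$conditions),
                                          collapse = ", ")))
  cat("  provenance:", x$provenance$source, "\n")
  invisible(x)
}

# Deterministic forward run for one condition, memoised in `cache` (an
# environment) because the forward model is deterministic: identical
# (params, confinement, horizon, resolution) always yield the same
# trajectory, and grid search re-visits them constantly.
simulate_condition <- function(params, conf, t_end, R0, N, cache = NULL) {
  key <- paste(c(unlist(unclass(params)[sapply(unclass(params), is.numeric)]),
                 params$feedback_stress, conf$mode, conf$c_H, conf$R0,
                 conf$p_bar, length(conf$events),
                 unlist(lapply(conf$events, unlist)), t_end, R0, N),
               collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- run_spheroid(params, conf, t_end = t_end, R0 = R0, N = N,
                      snapshot_times = c(0, t_end))
  out <- list(times = res$times, radius = res$radius,
              final = res$snapshots[[length(res$snapshots)]],
              final_state = res$state)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

density_summary <- function(final_snapshot, kind) {
  r <- final_snapshot$r
  R <- r[length(r)]
  switch(kind,
         average = (3 / R^3) * integrate_r2(final_snapshot$rho_c, r),
         center = final_snapshot$rho_c[1],
         stop("unknown density summary kind: ", kind))
}

# Apply one grid point / variant override to (params, conditions): model
# parameter names go to update_params; "c_H" (all gel conditions) or
# "c_H:<condition>" / "p_bar:<condition>" go to the confinement specs.
apply_overrides <- function(params, conditions, values) {
  pnames <- names(unclass(params))
  for (nm in names(values)) {
    val <- values[[nm]]
    if (nm %in% pnames) {
      args <- stats::setNames(list(val), nm)
      params <- do.call(update_params, c(list(params), args))
    } else if (nm == "c_H") {
      for (cn in names(conditions)) {
        if (conditions[[cn]]$mode == "gel") conditions[[cn]]$c_H <- val
      }
    } else if (grepl("^(c_H|p_bar):", nm)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      cn <- parts[2]
      if (!cn %in% names(conditions)) stop("unknown condition in grid: ", cn)
      conditions[[cn]][[parts[1]]] <- val
    } else {
      stop("unknown parameter in grid/override: ", nm)
    }
  }
  list(params = params, conditions = conditions)
}

#' Calibration objective
#'
#' Sum over conditions of squared radius residuals normalized by the
#' observation noise (or by the condition's mean observed radius when no sd
#' is given), plus squared normalized residuals of the relative-density
#' summaries, so radii and densities contribute on comparable scales. All
#' conditions share the tumor-associated parameters; only the confinement
#' differs. A failed forward run yields \code{Inf}.
#'
#' @param params A \code{\link{spheroid_params}} set shared by all
#'   conditions.
#' @param observations An \code{\link{observation_set}}.
#' @param R0 Initial radius of every simulated condition.
#' @param N Grid nodes per forward run.
#' @param cache Optional environment memoising forward runs (see
#'   \code{\link{grid_search}}).
#' @return Scalar objective (>= 0); lower is better.
#' @export
objective <- function(params, observations, R0 = 50, N = 80L,
                      cache = NULL) {
  robs <- observations$radius_obs
  dobs <- observations$density_obs
  conds <- observations$conditions
  t_end <- max(robs$time)
  sse <- 0
  sims <- list()
  tryCatch({
    for (cn in unique(c(robs$condition,
                        if (nrow(dobs)) c("free", dobs$condition)))) {
      sims[[cn]] <- simulate_condition(params, conds[[cn]], t_end, R0, N,
                                       cache)
    }
    for (cn in unique(robs$condition)) {
      sel <- robs$condition == cn
      sd_use <- ifelse(is.na(robs$sd[sel]) | robs$sd[sel] <= 0,
                       mean(robs$radius[sel]), robs$sd[sel])
      Rsim <- stats::approx(sims[[cn]]$times, sims[[cn]]$radius,
                            xout = robs$time[sel], rule = 2)$y
      sse <- sse + sum(((Rsim - robs$radius[sel]) / sd_use)^2)
    }
    if (nrow(dobs)) {
      for (i in seq_len(nrow(dobs))) {
        kind <- switch(dobs$kind[i],
                       average_ratio_vs_free = "average",
                       center_ratio_vs_free = "center",
                       stop("unknown density kind: ", dobs$kind[i]))
        ratio <- density_summary(sims[[dobs$condition[i]]]$final, kind) /
          density_summary(sims[["free"]]$final, kind)
        sd_use <- if (is.na(dobs$sd[i]) || dobs$sd[i] <= 0) abs(dobs$value[i])
                  else dobs$sd[i]
        sse <- sse + ((ratio - dobs$value[i]) / sd_use)^2
      }
    }
    sse
  }, error = function(e) Inf)
}

#' Exhaustive grid search with model-variant comparison
#'
#' Evaluates the \code{\link{objective}} on the full Cartesian grid of
#' candidate parameter values, for each model variant, and returns the best
#' point, the objective surface, the set of grid points within 10\% of the
#' best objective (the "10\% band"), and the corrected Akaike information
#' criterion per variant. Ties are broken by the first grid point in
#' iteration order (column-major over \code{expand.grid}), so results are
#' deterministic.
#'
#' Grid names are model parameter names (\code{beta}, \code{gamma_A}, ...)
#' or confinement parameters: \code{"c_H"} applies to every gel condition,
#' \code{"c_H:<condition>"} / \code{"p_bar:<condition>"} to one condition.
#'
#' Variants express the feedback comparison: each is a list with \code{fix}
#' (parameter overrides applied before the grid values) and \code{k} (the
#' parameter count charged to the variant in the AICc). The default pair
#' compares the full model (water-efflux feedback active; its two feedback
#' constants \code{gamma_A}, \code{Delta_A} are charged in addition to the
#' grid dimensions) against a no-feedback variant (\code{gamma_A = 0}).
#'
#' @param params Base \code{\link{spheroid_params}}.
#' @param grids Named list of numeric grid vectors.
#' @param observations An \code{\link{observation_set}}.
#' @param variants Named list of variants (see Details); \code{NULL} fits
#'   only the base model charged with \code{length(grids)} parameters.
#' @param R0,N Forward-run geometry and resolution.
#' @param cache Optional environment for memoising forward runs across
#'   calls (e.g. across seeds in a recovery study); created internally when
#'   \code{NULL}.
#' @return An object of class \code{"fit_result"}: list with \code{best}
#'   (named parameter values of the overall best variant's best point),
#'   \code{best_variant}, \code{objective}, \code{surface} (long data frame
#'   with grid coordinates, variant, objective), \code{band} (rows of the
#'   best variant within 10\% of its best objective), \code{aicc} (named
#'   vector), \code{n_obs}, and \code{grids}.
#' @export
grid_search <- function(params, grids, observations, variants = NULL,
                        R0 = 50, N = 80L, cache = NULL) {
  stopifnot(length(grids) > 0, all(lengths(grids) > 0),
            !is.null(names(grids)), all(nzchar(names(grids))))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(variants))
    variants <- list(fit = list(fix = list(), k = length(grids)))
  points <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  n_obs <- nrow(observations$radius_obs) + nrow(observations$density_obs)

  surface <- list()
  best <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    obj <- numeric(nrow(points))
    for (i in seq_len(nrow(points))) {
      vals <- c(v$fix, as.list(points[i, , drop = FALSE]))
      ap <- apply_overrides(params, observations$conditions, vals)
      obs_i <- observations
      obs_i$conditions <- ap$conditions
      obj[i] <- objective(ap$params, obs_i, R0 = R0, N = N, cache = cache)
    }
    i_best <- which.min(obj)   # first index on ties
    k <- if (is.null(v$k)) length(grids) else v$k
    best[[vn]] <- list(index = i_best, objective = obj[i_best],
                       params = as.list(points[i_best, , drop = FALSE]),
                       k = k,
                       aicc = aicc(obj[i_best], n_obs, k))
    surface[[vn]] <- cbind(points, variant = vn, objective = obj)
  }
  aiccs <- vapply(best, function(b) b$aicc, numeric(1))
  vn_best <- names(which.min(aiccs))
  surf_best <- surface[[vn_best]]
  band <- surf_best[surf_best$objective <=
                      1.1 * best[[vn_best]]$objective, , drop = FALSE]
  structure(list(best = best[[vn_best]]$params,
                 best_variant = vn_best,
                 objective = best[[vn_best]]$objective,
                 per_variant = best,
                 surface = do.call(rbind, surface),
                 band = band,
                 aicc = aiccs,
                 n_obs = n_obs,
                 grids = grids),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Grid-search fit over", paste(names(x$grids), collapse = ", "),
      sprintf("(%d points, %d observations)\n",
              nrow(x$surface) / length(x$aicc), x$n_obs))
  cat("  best variant:", x$best_variant, " objective:",
      format(x$objective, digits = 6), "\n")
  cat("  best point:",
      paste(names(x$best), "=", unlist(x$best), collapse = ", "), "\n")
  cat("  AICc:", paste(names(x$aicc), "=", round(x$aicc, 3),
                       collapse = ", "), "\n")
  cat(sprintf("  10%% band: %d grid point(s)\n", nrow(x$band)))
  invisible(x)
}

#' Corrected Akaike information criterion for least-squares fits
#'
#' The Gaussian-likelihood form for a sum-of-squares objective:
#' \deqn{AICc = n \ln(SSE/n) + 2k + \frac{2k(k+1)}{n-k-1},}
#' with \eqn{n} observations and \eqn{k} fitted parameters. The small-sample
#' correction term requires \eqn{n > k + 1}.
#'
#' @param sse Sum of squared (normalized) residuals.
#' @param n_obs Number of observations.
#' @param k_params Number of fitted parameters.
#' @return Scalar AICc (lower is better).
#' @export
aicc <- function(sse, n_obs, k_params) {
  if (n_obs <= k_params + 1)
    stop("AICc undefined: need n_obs > k_params + 1")
  n_obs * log(sse / n_obs) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Generate synthetic observations from known parameters
#'
#' Runs the forward model for each condition at the given (true) parameters,
#' samples the radius at the requested times, and perturbs every measurement
#' with independent Gaussian noise — a stand-in for spheroid
#' radius-over-time and relative-density data when no experimental table is
#' available. Density summaries (volume average and center value, as ratios
#' to the free condition) are taken at the last sampling time. Fully
#' reproducible from the seed.
#'
#' @param true_params The generating \code{\link{spheroid_params}}.
#' @param conditions Named list of \code{confinement_spec}s; must include
#'   \code{"free"} if density ratios are requested.
#' @param times Sampling times (may be irregular).
#' @param radius_sd Gaussian noise sd on radii (same length units).
#' @param density_sd Gaussian noise sd on density ratios; 0 disables noise.
#' @param density_kinds Character vector from
#'   \code{c("average_ratio_vs_free", "center_ratio_vs_free")}; summaries
#'   are produced for every non-free condition. Empty vector for none.
#' @param seed Integer seed.
#' @param R0,N Forward-run geometry and resolution.
#' @param cache Optional memoisation environment.
#' @return An \code{\link{observation_set}} with synthetic provenance.
#' @export
generate_observations <- function(true_params, conditions, times,
                                  radius_sd = 2, density_sd = 0.03,
                                  density_kinds = "average_ratio_vs_free",
                                  seed = 1, R0 = 50, N = 80L,
                                  cache = NULL) {
  stopifnot(length(times) > 0, all(times >= 0))
  times <- sort(times)
  t_end <- max(times)
  set.seed(seed)
  sims <- lapply(conditions, function(conf)
    simulate_condition(true_params, conf, t_end, R0, N, cache))
  rows <- list()
  for (cn in names(conditions)) {
    Rsim <- stats::approx(sims[[cn]]$times, sims[[cn]]$radius, xout = times,
                          rule = 2)$y
    rows[[cn]] <- data.frame(condition = cn, time = times,
                             radius = Rsim + stats::rnorm(length(times),
                                                          0, radius_sd),
                             sd = radius_sd)
  }
  radius_obs <- do.call(rbind, rows)
  rownames(radius_obs) <- NULL
  drows <- list()
  if (length(density_kinds)) {
    for (cn in setdiff(names(conditions), "free")) {
      for (kd in density_kinds) {
        kind <- switch(kd, average_ratio_vs_free = "average",
                       center_ratio_vs_free = "center",
                       stop("unknown density kind: ", kd))
        ratio <- density_summary(sims[[cn]]$final, kind) /
          density_summary(sims[["free"]]$final, kind)
        drows[[paste(cn, kd)]] <-
          data.frame(condition = cn, kind = kd,
                     value = ratio + stats::rnorm(1, 0, density_sd),
                     sd = density_sd)
      }
    }
  }
  density_obs <- if (length(drows)) do.call(rbind, drows) else NULL
  if (!is.null(density_obs)) rownames(density_obs) <- NULL
  observation_set(radius_obs, density_obs, conditions,
                  provenance = list(source = "synthetic", seed = seed,
                                    true_params = true_params,
                                    radius_sd = radius_sd,
                                    density_sd = density_sd))
}

#' Default variant pair for the feedback comparison
#'
#' The full model keeps the water-efflux feedback of \code{params} and is
#' charged its two feedback constants on top of the grid dimensions; the
#' no-feedback variant switches the stress feedbacks off
#' (\code{gamma_A = gamma_lambda = 0}) and is charged only the grid
#' dimensions.
#'
#' @param n_grid Number of grid dimensions in the search.
#' @return Named list of two variants for \code{\link{grid_search}}.
#' @export
feedback_variants <- function(n_grid) {
  list(feedback = list(fix = list(), k = n_grid + 2L),
       no_feedback = list(fix = list(gamma_A = 0, gamma_lambda = 0),
                          k = n_grid))
}
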