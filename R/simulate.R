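#' Run a phase-field sprouting simulation
#'
#' Integrates the governing dynamics with explicit Euler steps, re-imposing
#' Dirichlet reservoirs after every step, collecting snapshots at scheduled
#' physical times and (optionally) invoking tip sensing / MMP degradation
#' events at their cadence, which mutate the environment mid-run.
#'
#' @param env an `ecm_environment` from [compose_environment()].
#' @param params a [model_params()]; `params$dt` overrides `grid$dt` and must
#'   satisfy [stability_dt_max()].
#' @param grid a [grid_spec()].
#' @param res optional [reservoir_spec()].
#' @param initial a [phase_state()] (or matrix) giving phi at t = 0.
#' @param schedule_hours physical snapshot times (hours); the initial state is
#'   always snapshot 1 at 0 h.
#' @param degradation optional [degradation_params()]; `NULL` or
#'   `enabled = FALSE` runs the fundamental (static-environment) model.
#' @param direction advancement direction along y (-1: toward column 1).
#' @param dx lattice spacing in grid units.
#' @param verbose print progress (step index, hours, stability margin).
#' @return a `sprout_trajectory`: snapshot list, times, per-snapshot total
#'   phase and tip positions, degradation event log, initial/final
#'   environment.
#' @export
run_simulation <- function(env, params, grid, res = NULL, initial,
                           schedule_hours = numeric(0), degradation = NULL,
                           direction = -1L, dx = 1, verbose = FALSE) {
  stopifnot(inherits(env, "ecm_environment"), inherits(grid, "grid_spec"))
  if (!inherits(initial, "phase_state")) initial <- phase_state(initial)
  guard <- stability_dt_max(params, dx)
  if (params$dt > guard)
    stop(sprintf("dt = %g exceeds the explicit-stability guard %g", params$dt, guard))
  dt <- params$dt
  phi <- field_values(initial$phi)
  if (!identical(dim(phi), dim(field_values(env$C0))))
    stop("initial phi shape does not match environment")
  fl <- .res_flat(res, dim(phi))
  conserved <- params$env_grouping == "conserved"

  snap_steps <- sort(unique(round(hours_to_units(schedule_hours, grid) / dt)))
  snap_steps <- snap_steps[snap_steps > 0]
  deg_on <- !is.null(degradation) && isTRUE(degradation$enabled)
  if (deg_on && is.null(degradation$cadence_steps))
    degradation$cadence_steps <- default_cadence_steps(grid, dt)
  total <- if (length(snap_steps)) max(snap_steps) else 0L

  event_steps <- if (deg_on && total > 0)
    seq(degradation$cadence_steps, total, by = degradation$cadence_steps)
  else integer(0)
  bounds <- sort(unique(c(snap_steps, event_steps)))

  snap_phi <- list(phi)
  snap_t <- 0
  snap_sum <- sum(phi)
  tip0 <- tryCatch(locate_tip(phi, direction), error = function(e) NULL)
  tips <- data.frame(time_h = 0,
                     x_px = if (is.null(tip0)) NA_real_ else tip0$x,
                     y_px = if (is.null(tip0)) NA_real_ else tip0$y)
  events <- list()
  env0 <- env
  s <- 0L

  for (b in bounds) {
    n <- b - s
    if (n > 0) {
      out <- cpp_run_steps(phi, field_values(env$C0), params$M, params$eps,
                           dt, dx, n, fl$idx, fl$val, conserved,
                           params$overshoot_delta, min(n, 500L))
      if (!out$ok)
        stop(sprintf("instability at step %d (t = %.4g h): max |phi| = %.3g",
                     s + out$steps_done,
                     units_to_hours((s + out$steps_done) * dt, grid),
                     out$max_abs_phi))
      phi <- out$phi
      s <- b
    }
    if (b %in% event_steps) {
      ev <- degradation_event(phase_state(phi, s * dt, s), env, degradation,
                              direction)
      env <- ev$env
      events[[length(events) + 1]] <- data.frame(
        time_h = units_to_hours(s * dt, grid),
        tip_x = ev$tip$x, tip_y = ev$tip$y,
        heading_deg = ev$decision$angle_deg,
        target_x = ev$decision$target_center[1],
        target_y = ev$decision$target_center[2],
        hydrogel_mass = sum(field_values(env$hydrogel)))
    }
    if (b %in% snap_steps) {
      t_h <- units_to_hours(s * dt, grid)
      snap_phi[[length(snap_phi) + 1]] <- phi
      snap_t <- c(snap_t, t_h)
      snap_sum <- c(snap_sum, sum(phi))
      tp <- tryCatch(locate_tip(phi, direction), error = function(e) NULL)
      tips <- rbind(tips, data.frame(time_h = t_h,
                                     x_px = if (is.null(tp)) NA_real_ else tp$x,
                                     y_px = if (is.null(tp)) NA_real_ else tp$y))
      if (verbose)
        message(sprintf("step %d  t = %.3f h  sum(phi) = %.4f  margin = %.2f",
                        s, t_h, sum(phi), params$dt / guard))
    }
  }

  structure(list(times_h = snap_t, snapshots = snap_phi, sum_phi = snap_sum,
                 tip = tips,
                 events = if (length(events)) do.call(rbind, events) else NULL,
                 env_initial = env0, env_final = env, grid = grid,
                 params = params, direction = as.integer(direction), dx = dx),
            class = "sprout_trajectory")
}

#' Default degradation cadence: one sensing/degradation event per 0.275 h
#' of simulated time.
#' @param grid a [grid_spec()].
#' @param dt integration step (in-silico units).
#' @return integer number of integration steps between events.
#' @export
default_cadence_steps <- function(grid, dt = grid$dt) {
  max(1L, as.integer(round(hours_to_units(0.275, grid) / dt)))
}

#' @export
print.sprout_trajectory <- function(x, ...) {
  cat(sprintf("<sprout_trajectory> %d snapshots over %.3g h on %d x %d\n",
              length(x$times_h), max(x$times_h), nrow(x$snapshots[[1]]),
              ncol(x$snapshots[[1]])))
  if (!is.null(x$events))
    cat(sprintf("  %d degradation events, hydrogel mass %.4g -> %.4g\n",
                nrow(x$events), sum(field_values(x$env_initial$hydrogel)),
                sum(field_values(x$env_final$hydrogel))))
  invisible(x)
}
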