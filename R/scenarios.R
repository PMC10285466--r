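# Scenario builders for the canonical in-silico experiments: a simplified
# pore system (with/without cell contact), migration through an imaged or
# synthetic ECM with a carved open path, the small-spherical-reservoir
# variant, the same with tip-cell MMP degradation instead of a carved path,
# a static-tip degradation demo, and a no-chemoattractant control.
# Geometry is expressed in fractions of the domain so scenarios scale with
# the grid; defaults reproduce the canonical 200 x 200 setups.

.tanh_front <- function(grid, front_frac = 0.04, eps = 1) {
  j_f <- grid$ny - round(front_frac * grid$ny)
  jj <- matrix(seq_len(grid$ny), grid$nx, grid$ny, byrow = TRUE)
  tanh((jj - j_f) / (sqrt(2) * eps))
}

.tanh_disc <- function(grid, center, radius, eps = 1) {
  ii <- matrix(seq_len(grid$nx), grid$nx, grid$ny)
  jj <- matrix(seq_len(grid$ny), grid$nx, grid$ny, byrow = TRUE)
  d <- sqrt((ii - center[1])^2 + (jj - center[2])^2)
  tanh((radius - d) / (sqrt(2) * eps))
}

.edge_strip_mask <- function(grid, depth = 2L) {
  m <- matrix(FALSE, grid$nx, grid$ny)
  m[, (grid$ny - depth + 1L):grid$ny] <- TRUE
  m
}

.disc_mask <- function(grid, center, radius) {
  ii <- matrix(seq_len(grid$nx), grid$nx, grid$ny)
  jj <- matrix(seq_len(grid$ny), grid$nx, grid$ny, byrow = TRUE)
  (ii - center[1])^2 + (jj - center[2])^2 <= radius^2
}

.scenario <- function(name, grid, env, initial, reservoir, params,
                      degradation, schedule_hours, args, frozen = FALSE) {
  structure(list(name = name, grid = grid, env = env,
                 initial = phase_state(initial), reservoir = reservoir,
                 params = params, degradation = degradation,
                 schedule_hours = schedule_hours, direction = -1L,
                 frozen = frozen, args = args),
            class = "sprout_scenario")
}

#' @export
print.sprout_scenario <- function(x, ...) {
  cat(sprintf("<sprout_scenario '%s'> %d x %d, schedule {%s} h%s%s\n",
              x$name, x$grid$nx, x$grid$ny,
              paste(x$schedule_hours, collapse = ", "),
              if (!is.null(x$degradation) && x$degradation$enabled)
                ", degradation on" else "",
              if (x$frozen) ", frozen phase" else ""))
  invisible(x)
}

.resolve_ecm <- function(ecm_source, grid, seed, porosity = 0.5,
                         target_um = 40) {
  if (inherits(ecm_source, "scalar_field")) return(ecm_source)
  if (identical(ecm_source, "synthetic")) {
    spec <- ecm_gen_spec(porosity = porosity, target_mean_pore_um = target_um,
                         correlation_length_px = .calibrated_sigma(grid,
                           porosity, target_um, seed), seed = seed)
    return(generate_synthetic_ecm(spec, grid))
  }
  load_hydrogel_image(ecm_source, grid)
}

# Calibration is deterministic given (grid, porosity, target, seed); cache it
# for the session since the bisection regenerates dozens of fields.
.sf_cache <- new.env(parent = emptyenv())
.calibrated_sigma <- function(grid, porosity, target_um, seed) {
  key <- paste(grid$nx, grid$ny, grid$dx_um, porosity, target_um, seed,
               sep = "|")
  if (!is.null(.sf_cache[[key]])) return(.sf_cache[[key]])
  spec <- calibrate_ecm(ecm_gen_spec(porosity, target_um, NULL, seed), grid)
  .sf_cache[[key]] <- spec$correlation_length_px
  spec$correlation_length_px
}

#' Simplified pore scenario (contact vs distant)
#'
#' A flat endothelium at the high-y edge faces a single rectangular pore in
#' otherwise solid matrix, with a peaked chemoattractant rising from 0.1 at
#' the cells to 0.5 at the pore centre then decaying to 0 at the far edge.
#' With `contact = TRUE` the pore touches the cell front (C0 >= 0.1 there)
#' and sprouting is triggered; with `contact = FALSE` a dense band with
#' C0 = 0 separates cells from the pore and they stay immobile.
#'
#' @param contact logical; pore in contact with the cells or not.
#' @param grid a [grid_spec()].
#' @param params a [model_params()].
#' @param schedule_hours snapshot schedule (includes 27.5 h by default).
#' @return a `sprout_scenario`.
#' @export
scenario_fig4 <- function(contact = TRUE, grid = grid_spec(),
                          params = model_params(dt = grid$dt),
                          schedule_hours = c(2.75, 13.75, 27.5)) {
  nx <- grid$nx; ny <- grid$ny
  front_px <- round(0.04 * ny)
  # distant: the pore sits well beyond the diffuse interface (0.3 ny), so no
  # positive-C0 site is within reach of the cells or their tanh tail
  gap_px <- if (contact) 0 else round(0.3 * ny)
  pocket <- front_px + gap_px + c(0, round(0.2 * ny))  # y_px from cell edge
  halfw <- round(0.125 * nx)
  h <- matrix(1, nx, ny)
  jr <- (ny - pocket[2]):(ny - pocket[1])
  ir <- max(1, nx %/% 2 - halfw):min(nx, nx %/% 2 + halfw)
  h[ir, jr] <- 0
  peak_px <- mean(pocket)
  nu <- make_gradient(chemotactic_spec("peaked", start_level = 0.1,
                                       peak_level = 0.5,
                                       peak_pos_px = peak_px), grid)
  env <- compose_environment(nu, scalar_field(h, "hydrogel_density"),
                             gamma = 0.5, floor = 0, grid = grid)
  phi <- .tanh_front(grid, front_frac = 0.04, eps = params$eps)
  res <- combine_reservoirs(
    reservoir_spec(.edge_strip_mask(grid, 2L), 1),
    {
      m <- matrix(FALSE, nx, ny); m[, 1:2] <- TRUE
      reservoir_spec(m, -1)
    })
  .scenario(if (contact) "fig4b" else "fig4a", grid, env, phi, res, params,
            NULL, schedule_hours,
            args = list(name = if (contact) "fig4b" else "fig4a",
                        contact = contact))
}

#' ECM landscape with carved open path, lateral edge reservoir
#'
#' Porous hydrogel (synthetic by default, calibrated to a 40 um mean pore
#' size) with a carved open corridor from the endothelium toward the far
#' edge, a linear 0.3 -> 0.5 chemoattractant gradient increasing toward
#' y = 1, a spherical-cap endothelium attached to the high-y edge, and the
#' whole edge pinned as the cell reservoir.
#'
#' @param grid a [grid_spec()].
#' @param ecm_source `"synthetic"`, a file path readable by
#'   [load_hydrogel_image()], or a prebuilt hydrogel [scalar_field()].
#' @param seed RNG seed for the synthetic ECM.
#' @param params a [model_params()].
#' @param carve_path carve the corridor (TRUE here; the degradation variant
#'   sets it FALSE).
#' @param schedule_hours snapshot schedule (includes 96.25 h by default).
#' @return a `sprout_scenario`.
#' @export
scenario_fig5 <- function(grid = grid_spec(), ecm_source = "synthetic",
                          seed = 1L, params = model_params(dt = grid$dt),
                          carve_path = TRUE,
                          schedule_hours = c(2.75, 27.5, 55, 96.25)) {
  nx <- grid$nx; ny <- grid$ny
  h <- .resolve_ecm(ecm_source, grid, seed)
  if (carve_path) h <- carve_open_path(h, .default_path(grid))
  nu <- make_gradient(chemotactic_spec("linear", alpha = 0.1, beta = 0.3), grid)
  env <- compose_environment(nu, h, gamma = 0.5, floor = 0, grid = grid)
  cap <- .tanh_disc(grid, c(nx / 2, ny), radius = round(0.15 * ny),
                    eps = params$eps)
  res <- reservoir_spec(.edge_strip_mask(grid, 2L), 1)
  .scenario("fig5", grid, env, cap, res, params, NULL, schedule_hours,
            args = list(name = "fig5", seed = seed,
                        ecm_source = if (is.character(ecm_source))
                          ecm_source else "synthetic"))
}

.default_path <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  path_spec(rbind(c(nx / 2, ny),
                  c(nx / 2, round(0.65 * ny)),
                  c(round(nx / 2 + 0.12 * nx), round(0.33 * ny)),
                  c(nx / 2, 1)),
            width_px = max(4, round(0.05 * ny)))
}

#' Small spherical reservoir variant
#'
#' As [scenario_fig5()] but the initial condition is a small sphere of cells
#' sitting on the corridor axis near the high-y side, and the Dirichlet
#' reservoir is that same sphere (the initial distribution), isolating the
#' tip advancement.
#'
#' @inheritParams scenario_fig5
#' @return a `sprout_scenario`.
#' @export
scenario_fig6 <- function(grid = grid_spec(), ecm_source = "synthetic",
                          seed = 1L, params = model_params(dt = grid$dt),
                          carve_path = TRUE,
                          schedule_hours = c(2.75, 27.5, 55, 96.25)) {
  nx <- grid$nx; ny <- grid$ny
  h <- .resolve_ecm(ecm_source, grid, seed)
  if (carve_path) h <- carve_open_path(h, .default_path(grid))
  nu <- make_gradient(chemotactic_spec("linear", alpha = 0.1, beta = 0.3), grid)
  env <- compose_environment(nu, h, gamma = 0.5, floor = 0, grid = grid)
  center <- c(nx / 2, ny - round(0.12 * ny))
  radius <- max(4, round(0.075 * ny))
  phi <- .tanh_disc(grid, center, radius, eps = params$eps)
  res <- reservoir_spec(.disc_mask(grid, center, radius), 1)
  .scenario("fig6", grid, env, phi, res, params, NULL, schedule_hours,
            args = list(name = "fig6", seed = seed,
                        ecm_source = if (is.character(ecm_source))
                          ecm_source else "synthetic"))
}

#' Degradation variant: no carved path, tip-cell MMP degradation on
#'
#' As [scenario_fig6()] but the corridor is not carved; instead the tip cell
#' senses the matrix and degrades it (default power 0.2, 10-px sensing
#' radius), self-generating a pore.
#'
#' @inheritParams scenario_fig5
#' @param degradation a [degradation_params()].
#' @return a `sprout_scenario`.
#' @export
scenario_fig7 <- function(grid = grid_spec(), ecm_source = "synthetic",
                          seed = 1L, params = model_params(dt = grid$dt),
                          degradation = degradation_params(),
                          schedule_hours = c(2.75, 27.5, 55, 82.5)) {
  sc <- scenario_fig6(grid, ecm_source, seed, params, carve_path = FALSE,
                      schedule_hours = schedule_hours)
  sc$name <- "fig7"
  sc$degradation <- degradation
  sc$args <- list(name = "fig7", seed = seed,
                  ecm_source = if (is.character(ecm_source))
                    ecm_source else "synthetic")
  sc
}

#' Static-tip degradation demo
#'
#' Phase dynamics are frozen: an immobile tip cell repeatedly senses and
#' degrades the matrix ahead of it, one event per "time step", reproducing
#' the 0/5/10-event depletion sequence. Run it with
#' [run_static_degradation()].
#'
#' @param grid a [grid_spec()].
#' @param ecm_source as in [scenario_fig5()].
#' @param seed RNG seed for the synthetic ECM.
#' @param degradation a [degradation_params()] (cadence forced to 1 event
#'   per step).
#' @return a frozen `sprout_scenario`.
#' @export
scenario_fig3_static_tip <- function(grid = grid_spec(64L, 64L),
                                     ecm_source = "synthetic", seed = 1L,
                                     degradation = degradation_params()) {
  nx <- grid$nx; ny <- grid$ny
  h <- .resolve_ecm(ecm_source, grid, seed,
                    target_um = min(40, 0.3 * ny * grid$dx_um))
  nu <- make_gradient(chemotactic_spec("linear", alpha = 0.1, beta = 0.3), grid)
  env <- compose_environment(nu, h, gamma = 0.5, floor = 0, grid = grid)
  # a narrow finger of cells reaching from the edge to mid-domain
  phi <- matrix(-1, nx, ny)
  ir <- max(1, nx %/% 2 - 2):min(nx, nx %/% 2 + 2)
  phi[ir, (ny - round(0.4 * ny)):ny] <- 1
  degradation$cadence_steps <- 1L
  .scenario("fig3", grid, env, phi, NULL, model_params(dt = grid$dt),
            degradation, numeric(0), args = list(name = "fig3", seed = seed),
            frozen = TRUE)
}

#' Run a frozen-phase degradation sequence
#'
#' Applies `n_events` sensing/degradation events to a frozen scenario (the
#' tip never moves) and records the hydrogel field after each requested
#' event count.
#'
#' @param sc a frozen `sprout_scenario` (see [scenario_fig3_static_tip()]).
#' @param n_events number of events to apply.
#' @param record_at event counts at which to store the hydrogel state
#'   (0 = initial).
#' @return list with `hydrogel` (named list of fields), `decisions`, `tip`.
#' @export
run_static_degradation <- function(sc, n_events = 10L,
                                   record_at = c(0L, 5L, 10L)) {
  stopifnot(inherits(sc, "sprout_scenario"), isTRUE(sc$frozen))
  env <- sc$env
  state <- sc$initial
  tip <- locate_tip(state$phi, sc$direction)
  out <- list()
  if (0L %in% record_at) out[["0"]] <- env$hydrogel
  decisions <- list()
  for (k in seq_len(n_events)) {
    ev <- degradation_event(state, env, sc$degradation, sc$direction)
    env <- ev$env
    decisions[[k]] <- ev$decision
    if (k %in% record_at) out[[as.character(k)]] <- env$hydrogel
  }
  list(hydrogel = out, decisions = decisions, tip = tip, env_final = env)
}

#' No-chemoattractant control
#'
#' Flat endothelium with an edge reservoir, uniform baseline chemoattractant
#' confined to the pore space (no directional cue), no carved path, no
#' degradation, 48 h horizon. Cells are expected to fill nearby pores but
#' not to migrate across the matrix.
#'
#' @inheritParams scenario_fig5
#' @return a `sprout_scenario`.
#' @export
scenario_no_vegf <- function(grid = grid_spec(), ecm_source = "synthetic",
                             seed = 1L, params = model_params(dt = grid$dt),
                             schedule_hours = c(2.75, 24, 48)) {
  h <- .resolve_ecm(ecm_source, grid, seed)
  vh <- field_values(h)
  nu <- matrix(0.3, grid$nx, grid$ny)
  nu[vh >= 0.5] <- 0  # baseline level exists only in pore space
  env <- compose_environment(scalar_field(nu, "nu_c"), h, gamma = 0.5,
                             floor = 0, grid = grid)
  phi <- .tanh_front(grid, front_frac = 0.04, eps = params$eps)
  res <- reservoir_spec(.edge_strip_mask(grid, 2L), 1)
  .scenario("no_vegf", grid, env, phi, res, params, NULL, schedule_hours,
            args = list(name = "no_vegf", seed = seed,
                        ecm_source = if (is.character(ecm_source))
                          ecm_source else "synthetic"))
}

#' Execute a scenario
#'
#' @param sc a `sprout_scenario`.
#' @param verbose forwarded to [run_simulation()].
#' @return a `sprout_trajectory`.
#' @export
run_scenario <- function(sc, verbose = FALSE) {
  stopifnot(inherits(sc, "sprout_scenario"))
  if (sc$frozen)
    stop("frozen scenario: use run_static_degradation()")
  run_simulation(sc$env, sc$params, sc$grid, sc$reservoir, sc$initial,
                 sc$schedule_hours, sc$degradation, sc$direction,
                 verbose = verbose)
}

#' Build a named scenario
#'
#' Dispatch helper used by the CLI: rebuilds any canonical scenario from its
#' name plus seed (and the contact flag for the simplified-pore pair), which
#' is all the information a config needs for bit-identical reconstruction.
#'
#' @param name one of `"fig3"`, `"fig4a"`, `"fig4b"`, `"fig5"`, `"fig6"`,
#'   `"fig7"`, `"no_vegf"`.
#' @param grid a [grid_spec()].
#' @param seed RNG seed.
#' @param ecm_source see [scenario_fig5()].
#' @return a `sprout_scenario`.
#' @export
build_scenario <- function(name, grid = grid_spec(), seed = 1L,
                           ecm_source = "synthetic") {
  switch(name,
    fig3 = scenario_fig3_static_tip(grid, ecm_source, seed),
    fig4a = scenario_fig4(contact = FALSE, grid = grid),
    fig4b = scenario_fig4(contact = TRUE, grid = grid),
    fig5 = scenario_fig5(grid, ecm_source, seed),
    fig6 = scenario_fig6(grid, ecm_source, seed),
    fig7 = scenario_fig7(grid, ecm_source, seed),
    no_vegf = scenario_no_vegf(grid, ecm_source, seed),
    stop(sprintf("unknown scenario '%s'", name)))
}
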