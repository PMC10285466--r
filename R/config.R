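#' Default configuration
#'
#' All keys with their canonical defaults (200 x 200 grid of 3.85 um pixels,
#' dt = 1e-3, M = eps = 1, linear 0.1 y + 0.3 gradient, gamma = 0.5,
#' synthetic 40-um-pore ECM, degradation off).
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  list(
    grid = list(nx = 200L, ny = 200L, dx_um = 3.85, time_unit_h = 2.75e-3,
                dt = 1e-3),
    model = list(M = 1, eps = 1, env_grouping = "conserved",
                 overshoot_delta = 0.1),
    gradient = list(profile = "linear", alpha = 0.1, beta = 0.3,
                    direction = -1L, start_level = 0.1, peak_level = 0.5,
                    peak_pos_px = NULL),
    ecm = list(source = "synthetic", image_path = NULL, porosity = 0.5,
               target_mean_pore_um = 40, correlation_length_px = NULL,
               seed = 1L),
    env = list(gamma = 0.5, floor = 0),
    path = list(enabled = FALSE, waypoints = NULL, width_px = 10),
    degradation = list(enabled = FALSE, sensing_radius_px = 10, power = 0.2,
                       sigma_px = 5, cadence_steps = NULL,
                       heading_halfangle_deg = 60, heading_step_deg = 15),
    run = list(until_hours = 27.5, snapshot_every_hours = 2.75),
    scenario = list(name = NULL, seed = 1L)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s'", here))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key '%s' must be a section", here))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], here)
    } else {
      # [key] <- list(...) keeps explicit nulls instead of deleting the entry
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Load and validate a JSON configuration file
#'
#' Missing keys are filled with [default_config()] values; unknown keys are
#' rejected with their full key path; `grid.dt` is checked against the
#' explicit-stability guard.
#'
#' @param path JSON file; an empty file or `{}` yields the full defaults.
#' @return the resolved config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = TRUE)
  cfg <- .merge_config(default_config(), user)
  guard <- stability_dt_max(model_params(M = cfg$model$M, eps = cfg$model$eps,
                                         dt = cfg$grid$dt))
  if (cfg$grid$dt > guard)
    stop(sprintf("grid.dt = %g exceeds the stability guard %g",
                 cfg$grid$dt, guard))
  cfg
}

#' Write a configuration to JSON
#' @param cfg a config list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
emit_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Build a scenario from a resolved configuration
#'
#' If `scenario.name` is set the corresponding canonical scenario is rebuilt
#' (bit-identical given the seed). Otherwise a generic setup is assembled
#' from the gradient/ecm/path/env sections: flat endothelium at the high-y
#' edge with an edge reservoir, snapshots every `run.snapshot_every_hours`
#' up to `run.until_hours`.
#'
#' @param cfg a config list from [load_config()].
#' @return a `sprout_scenario`.
#' @export
scenario_from_config <- function(cfg) {
  grid <- grid_spec(cfg$grid$nx, cfg$grid$ny, cfg$grid$dx_um,
                    cfg$grid$time_unit_h, cfg$grid$dt)
  if (!is.null(cfg$scenario$name))
    return(build_scenario(cfg$scenario$name, grid,
                          seed = cfg$scenario$seed %||% 1L,
                          ecm_source = if (identical(cfg$ecm$source, "image"))
                            cfg$ecm$image_path else "synthetic"))
  params <- model_params(cfg$model$M, cfg$model$eps, cfg$grid$dt,
                         cfg$model$env_grouping, cfg$model$overshoot_delta)
  gs <- cfg$gradient
  nu <- make_gradient(chemotactic_spec(gs$profile, gs$alpha, gs$beta,
                                       direction = gs$direction,
                                       start_level = gs$start_level,
                                       peak_level = gs$peak_level,
                                       peak_pos_px = gs$peak_pos_px), grid)
  h <- switch(cfg$ecm$source,
    synthetic = generate_synthetic_ecm(
      ecm_gen_spec(cfg$ecm$porosity, cfg$ecm$target_mean_pore_um,
                   cfg$ecm$correlation_length_px, cfg$ecm$seed), grid),
    image = load_hydrogel_image(cfg$ecm$image_path, grid),
    none = scalar_field(matrix(0, grid$nx, grid$ny), "hydrogel_density"),
    stop(sprintf("unknown ecm.source '%s'", cfg$ecm$source)))
  if (isTRUE(cfg$path$enabled)) {
    wp <- cfg$path$waypoints
    if (is.null(wp)) stop("path.enabled = true requires path.waypoints")
    if (!is.matrix(wp)) wp <- do.call(rbind, wp)
    h <- carve_open_path(h, path_spec(wp, cfg$path$width_px))
  }
  env <- compose_environment(nu, h, cfg$env$gamma, cfg$env$floor, grid)
  deg <- if (isTRUE(cfg$degradation$enabled))
    degradation_params(cfg$degradation$sensing_radius_px,
                       cfg$degradation$power, cfg$degradation$sigma_px,
                       cfg$degradation$cadence_steps,
                       cfg$degradation$heading_halfangle_deg,
                       cfg$degradation$heading_step_deg)
  else NULL
  sched <- seq(cfg$run$snapshot_every_hours, cfg$run$until_hours,
               by = cfg$run$snapshot_every_hours)
  phi <- .tanh_front(grid, front_frac = 0.04, eps = params$eps)
  res <- reservoir_spec(.edge_strip_mask(grid, 2L), 1)
  .scenario("custom", grid, env, phi, res, params, deg, sched,
            args = list(name = "custom"))
}

#' Serialize a canonical scenario to a config
#' @param sc a `sprout_scenario` built by one of the `scenario_*` builders.
#' @return a config list whose [scenario_from_config()] rebuild is identical.
#' @export
scenario_to_config <- function(sc) {
  cfg <- default_config()
  cfg$grid <- list(nx = sc$grid$nx, ny = sc$grid$ny, dx_um = sc$grid$dx_um,
                   time_unit_h = sc$grid$time_unit_h, dt = sc$grid$dt)
  cfg$scenario$name <- sc$args$name
  cfg$scenario$seed <- sc$args$seed %||% 1L
  cfg
}
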