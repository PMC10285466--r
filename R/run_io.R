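# Run persistence: a run directory holds a JSON manifest, one full-precision
# CSV per phi snapshot, CSVs for the environment fields, the tip track and
# the degradation event log. Text formats keep runs portable and diffable;
# values round-trip exactly via %.17g.

.write_mat <- function(m, path) {
  write.table(formatC(unclass(m), format = "g", digits = 17), path,
              sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
}

.read_mat <- function(path) {
  as.matrix(read.table(path, sep = ",", header = FALSE,
                       colClasses = "numeric"))
}

#' Save a trajectory to a run directory
#'
#' @param traj a `sprout_trajectory`.
#' @param run_dir directory to create/populate.
#' @return `run_dir`, invisibly.
#' @export
save_run <- function(traj, run_dir) {
  stopifnot(inherits(traj, "sprout_trajectory"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  snaps <- sprintf("snapshot_%03d.csv", seq_along(traj$snapshots) - 1L)
  for (k in seq_along(traj$snapshots))
    .write_mat(traj$snapshots[[k]], file.path(run_dir, snaps[k]))
  .write_mat(traj$env_initial$hydrogel, file.path(run_dir, "hydrogel_initial.csv"))
  .write_mat(traj$env_final$hydrogel, file.path(run_dir, "hydrogel_final.csv"))
  .write_mat(traj$env_initial$nu_c, file.path(run_dir, "nu_c.csv"))
  tt <- traj$tip
  tt$sum_phi <- traj$sum_phi
  write.table(tt, file.path(run_dir, "tip_track.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  if (!is.null(traj$events))
    write.table(traj$events, file.path(run_dir, "events.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "sproutfield",
    version = as.character(utils::packageVersion("sproutfield")),
    grid = traj$grid[c("nx", "ny", "dx_um", "time_unit_h", "dt")],
    params = unclass(traj$params),
    env = list(gamma = traj$env_initial$gamma, floor = traj$env_initial$floor),
    direction = traj$direction, dx = traj$dx,
    times_h = traj$times_h, sum_phi = traj$sum_phi,
    snapshots = snaps, has_events = !is.null(traj$events))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run_dir)
}

#' Load a trajectory from a run directory
#'
#' @param run_dir a directory written by [save_run()].
#' @return the reconstructed `sprout_trajectory` (numerically identical).
#' @export
load_run <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop(sprintf("no manifest in '%s'", run_dir))
  mf <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE)
  missing <- mf$snapshots[!file.exists(file.path(run_dir, mf$snapshots))]
  if (length(missing))
    stop(sprintf("run directory incomplete, missing: %s",
                 paste(missing, collapse = ", ")))
  grid <- grid_spec(mf$grid$nx, mf$grid$ny, mf$grid$dx_um,
                    mf$grid$time_unit_h, mf$grid$dt)
  params <- model_params(mf$params$M, mf$params$eps, mf$params$dt,
                         mf$params$env_grouping, mf$params$overshoot_delta)
  snapshots <- lapply(file.path(run_dir, mf$snapshots), .read_mat)
  nu_c <- scalar_field(.read_mat(file.path(run_dir, "nu_c.csv")), "nu_c")
  h0 <- scalar_field(.read_mat(file.path(run_dir, "hydrogel_initial.csv")),
                     "hydrogel_density")
  h1 <- scalar_field(.read_mat(file.path(run_dir, "hydrogel_final.csv")),
                     "hydrogel_density")
  tt <- read.table(file.path(run_dir, "tip_track.csv"), sep = ",",
                   header = TRUE)
  events <- if (isTRUE(mf$has_events))
    read.table(file.path(run_dir, "events.csv"), sep = ",", header = TRUE)
  else NULL
  structure(list(times_h = mf$times_h, snapshots = snapshots,
                 sum_phi = vapply(snapshots, sum, numeric(1)),
                 tip = tt[c("time_h", "x_px", "y_px")],
                 events = events,
                 env_initial = compose_environment(nu_c, h0, mf$env$gamma,
                                                   mf$env$floor, grid),
                 env_final = compose_environment(nu_c, h1, mf$env$gamma,
                                                 mf$env$floor, grid),
                 grid = grid, params = params,
                 direction = as.integer(mf$direction), dx = mf$dx),
            class = "sprout_trajectory")
}
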