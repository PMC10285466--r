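#' Chemoattractant profile specification
#'
#' Describes the quasi-static chemotactic factor field nu_c along the
#' advancement axis. The default linear profile is the canonical gradient
#' `0.1 y + 0.3` with `y` measured from the cell-side edge in units of
#' `ny / 2` grid points, so that the profile spans 0.3 at the cells to 0.5
#' at the far edge of the domain and lands on the composite-field band
#' limits. Values are always confined to [0, 0.5].
#'
#' @param profile one of `"linear"`, `"peaked"`, `"uniform"`, `"zero"`.
#' @param alpha gradient slope per normalized coordinate unit (linear).
#' @param beta offset (linear) or constant level (uniform).
#' @param axis advancement axis; only `"y"` is supported.
#' @param direction -1 if cells start at the high-index edge and advance
#'   toward index 1 (the default), +1 for the mirrored setup.
#' @param start_level,peak_level,peak_pos_px peaked profile: level at the
#'   cell-side edge, level at the peak, and peak distance from the cell-side
#'   edge in pixels. The profile rises linearly from `start_level` to
#'   `peak_level` at `peak_pos_px`, then decays linearly to 0 at the far edge.
#' @return an object of class `chemotactic_spec`.
#' @export
chemotactic_spec <- function(profile = c("linear", "peaked", "uniform", "zero"),
                             alpha = 0.1, beta = 0.3, axis = "y",
                             direction = -1L, start_level = 0.1,
                             peak_level = 0.5, peak_pos_px = NULL) {
  profile <- match.arg(profile)
  stopifnot(identical(axis, "y"), direction %in% c(-1L, 1L))
  if (profile == "uniform" && (beta < 0 || beta > 0.5))
    stop("uniform chemoattractant level must lie in [0, 0.5]")
  if (profile == "peaked") {
    stopifnot(start_level >= 0, peak_level <= 0.5, peak_level >= start_level)
  }
  structure(list(profile = profile, alpha = alpha, beta = beta, axis = axis,
                 direction = as.integer(direction), start_level = start_level,
                 peak_level = peak_level, peak_pos_px = peak_pos_px),
            class = "chemotactic_spec")
}

#' Build the chemoattractant field on a grid
#'
#' @param spec a [chemotactic_spec()].
#' @param grid a [grid_spec()].
#' @return a [scalar_field()] with role `nu_c`, values in [0, 0.5].
#' @examples
#' g <- grid_spec()
#' nu <- make_gradient(chemotactic_spec("linear"), g)
#' range(nu)  # 0.3 at the cell edge up to ~0.5 at the far edge
#' @export
make_gradient <- function(spec, grid) {
  stopifnot(inherits(spec, "chemotactic_spec"), inherits(grid, "grid_spec"))
  ny <- grid$ny
  j <- seq_len(ny)
  ypx <- .y_from_cell_edge(j, ny, spec$direction)
  prof <- switch(spec$profile,
    zero = rep(0, ny),
    uniform = rep(spec$beta, ny),
    linear = spec$alpha * ypx / (ny / 2) + spec$beta,
    peaked = {
      peak <- spec$peak_pos_px %||% (ny / 2)
      span <- max(ypx)
      if (peak <= 0 || peak >= span) stop("peak_pos_px must be inside the domain")
      up <- spec$start_level + (spec$peak_level - spec$start_level) * ypx / peak
      down <- spec$peak_level * (span - ypx) / (span - peak)
      ifelse(ypx <= peak, up, down)
    })
  prof <- pmin(pmax(prof, 0), 0.5)
  scalar_field(matrix(prof, nrow = grid$nx, ncol = ny, byrow = TRUE),
               "nu_c", grid)
}
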