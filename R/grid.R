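#' Simulation grid specification
#'
#' Defines the lattice and its physical calibration. The defaults are the
#' canonical calibration: a 200 x 200 grid of 3.85 um pixels (770 um domain),
#' one in-silico time unit = 2.75e-3 h, and an integration step dt = 1e-3
#' in-silico units (2.75e-6 h).
#'
#' @param nx,ny number of grid points in x (transverse) and y (advancement
#'   axis). Must be >= 8.
#' @param dx_um physical length of one grid point, micrometres.
#' @param time_unit_h physical hours represented by one in-silico time unit.
#' @param dt in-silico time advanced per integration step.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(100, 100, dx_um = 7.7, time_unit_h = 5.5e-3)
#' hours_to_units(27.5, g)
#' @export
grid_spec <- function(nx = 200L, ny = 200L, dx_um = 3.85,
                      time_unit_h = 2.75e-3, dt = 1e-3) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 8L, ny >= 8L, dx_um > 0, time_unit_h > 0, dt > 0)
  structure(list(nx = nx, ny = ny, dx_um = dx_um,
                 time_unit_h = time_unit_h, dt = dt),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d, dx = %g um (%g x %g um), 1 unit = %g h, dt = %g\n",
              x$nx, x$ny, x$dx_um, x$nx * x$dx_um, x$ny * x$dx_um,
              x$time_unit_h, x$dt))
  invisible(x)
}

#' Convert between simulated hours and in-silico time units
#' @param hours,units time in physical hours / in-silico units.
#' @param grid a [grid_spec()].
#' @return numeric time in the other unit system.
#' @export
hours_to_units <- function(hours, grid) hours / grid$time_unit_h

#' @rdname hours_to_units
#' @export
units_to_hours <- function(units, grid) units * grid$time_unit_h

field_roles <- c("phi", "B_phi", "nu_c", "nu_ecm", "C0", "hydrogel_density")

#' Scalar lattice field
#'
#' A 2-D real lattice on a [grid_spec()] carrying a role tag (`phi`, `nu_c`,
#' `C0`, `hydrogel_density`, ...). It is an ordinary matrix underneath;
#' `field_values()` strips the class for raw numerics. Row index is x,
#' column index is y (the advancement axis).
#'
#' @param values numeric matrix, all entries finite.
#' @param role one of `r paste(field_roles, collapse = ", ")`.
#' @param grid optional [grid_spec()]; if supplied the shape is checked.
#' @return a `scalar_field` (matrix subclass).
#' @export
scalar_field <- function(values, role, grid = NULL) {
  role <- match.arg(role, field_roles)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("scalar_field values must be finite numerics")
  if (!is.null(grid) && !identical(dim(values), c(grid$nx, grid$ny)))
    stop(sprintf("field shape %d x %d does not match grid %d x %d",
                 nrow(values), ncol(values), grid$nx, grid$ny))
  structure(values, role = role, class = c("scalar_field", class(values)))
}

#' @rdname scalar_field
#' @param f a `scalar_field` or plain matrix.
#' @export
field_values <- function(f) {
  v <- unclass(f)
  attr(v, "role") <- NULL
  v
}

#' @rdname scalar_field
#' @export
field_role <- function(f) attr(f, "role")

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field role=%s> %d x %d, range [%.4g, %.4g]\n",
              attr(x, "role") %||% "?", nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# y coordinate in pixels measured from the cell-side edge (direction = -1:
# cells start at column ny and advance toward column 1).
.y_from_cell_edge <- function(j, ny, direction = -1L) {
  if (direction < 0) ny - j else j - 1
}
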