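#' Phase-field model parameters
#'
#' @param M mobility (> 0, dimensionless, default 1).
#' @param eps interface width parameter in grid units (default 1); the 1-D
#'   equilibrium interface is `tanh(y / (sqrt(2) * eps))`.
#' @param dt in-silico integration step. Must satisfy the explicit-stability
#'   guard `dt <= 0.8 * dx^4 / (32 * M * eps^2)` (checked against the grid at
#'   run time by [run_simulation()]).
#' @param env_grouping `"conserved"` (default: the environment-effect term is
#'   folded into the chemical potential inside the outer Laplacian, keeping
#'   interior dynamics exactly conserved so all phase injection comes from the
#'   Dirichlet reservoirs) or `"additive"` (the term is added outside the
#'   outer Laplacian, as the printed grouping of the governing equation).
#'   The additive grouping makes the bulk medium linearly unstable wherever
#'   `C0 > 0` (growth rate `4 eps^2 C0^2` at wavenumber 0), so isolated
#'   positive-`C0` pores nucleate spontaneously over long horizons; the
#'   conserved grouping is unconditionally bulk-stable and reproduces the
#'   quiescence of cells distant from the chemoattractant. See the methods
#'   vignette.
#' @param overshoot_delta benign overshoot tolerance: integration aborts when
#'   `|phi| > 1 + overshoot_delta` (blow-up diagnostic).
#' @return an object of class `model_params`.
#' @export
model_params <- function(M = 1, eps = 1, dt = 1e-3,
                         env_grouping = c("conserved", "additive"),
                         overshoot_delta = 0.1) {
  env_grouping <- match.arg(env_grouping)
  stopifnot(M > 0, eps > 0, dt > 0, overshoot_delta > 0)
  structure(list(M = M, eps = eps, dt = dt, env_grouping = env_grouping,
                 overshoot_delta = overshoot_delta),
            class = "model_params")
}

#' Maximum stable explicit Euler step
#'
#' The stiffest term is the biharmonic `M * eps^2 * lap(lap(phi))`; its
#' explicit-Euler stability limit on a 5-point stencil is
#' `dx^4 / (32 * M * eps^2)`. [run_simulation()] refuses `dt` above 0.8x this.
#'
#' @param params a [model_params()].
#' @param dx lattice spacing in grid units (1 by convention).
#' @return the guard value (0.8x the linear-stability bound).
#' @export
stability_dt_max <- function(params, dx = 1) {
  0.8 * dx^4 / (32 * params$M * params$eps^2)
}

#' Phase state: the order-parameter field plus the simulation clock
#'
#' @param phi a [scalar_field()] or matrix; values in `[-1 - d, 1 + d]`.
#' @param t_insilico elapsed in-silico time.
#' @param step_index integration steps taken.
#' @return an object of class `phase_state`.
#' @export
phase_state <- function(phi, t_insilico = 0, step_index = 0L) {
  v <- field_values(phi)
  stopifnot(all(is.finite(v)))
  structure(list(phi = scalar_field(v, "phi"), t_insilico = t_insilico,
                 step_index = as.integer(step_index)),
            class = "phase_state")
}

#' Dirichlet reservoir specification
#'
#' Sites where phi is re-pinned after every integration step, modelling an
#' endothelium as an unlimited cell source (value +1) or a medium sink (-1).
#'
#' @param mask logical matrix of pinned sites.
#' @param value +1 or -1, or a numeric matrix giving per-site values.
#' @return an object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(mask, value = 1) {
  mask <- as.matrix(mask)
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("reservoir mask is empty")
  if (length(value) == 1) {
    stopifnot(abs(value) == 1)
  } else {
    value <- as.matrix(value)
    stopifnot(identical(dim(value), dim(mask)), all(abs(value[mask]) == 1))
  }
  structure(list(mask = mask, value = value), class = "reservoir_spec")
}

#' Merge several reservoirs into one
#' @param ... [reservoir_spec()] objects on the same grid. Later reservoirs
#'   win on overlapping sites.
#' @return a single [reservoir_spec()] with a per-site value matrix.
#' @export
combine_reservoirs <- function(...) {
  specs <- list(...)
  stopifnot(length(specs) >= 1)
  mask <- specs[[1]]$mask & FALSE
  vals <- matrix(0, nrow(mask), ncol(mask))
  for (r in specs) {
    mask <- mask | r$mask
    vals[r$mask] <- if (length(r$value) == 1) r$value else r$value[r$mask]
  }
  reservoir_spec(mask, vals)
}

.res_flat <- function(res, dims) {
  if (is.null(res)) return(list(idx = integer(0), val = numeric(0)))
  stopifnot(identical(dim(res$mask), dims))
  idx <- which(res$mask)
  val <- if (length(res$value) == 1) rep(res$value, length(idx)) else res$value[idx]
  list(idx = idx - 1L, val = val)
}

#' Five-point stencil Laplacian
#'
#' Mirror (no-flux) closure at the boundary: the ghost value equals the edge
#' value, making the stencil a discrete flux divergence with zero boundary
#' flux (so the Laplacian of any field sums to zero to rounding).
#'
#' @param f matrix or [scalar_field()].
#' @param dx lattice spacing (grid units).
#' @return matrix of the same shape.
#' @export
laplacian_5pt <- function(f, dx = 1) {
  cpp_laplacian5(field_values(f), dx)
}

#' Environment interaction term B_phi
#'
#' `B_phi = eps * C0 * (phi^2 - 1)`: proportional to the composite
#' environment and localized at the diffuse interface, vanishing in both
#' bulk phases so the environment acts only where the cell boundary is.
#'
#' @param phi,C0 matrices or [scalar_field()]s of matching shape.
#' @param eps interface width parameter.
#' @return a [scalar_field()] with role `B_phi`.
#' @export
interaction_term <- function(phi, C0, eps = 1) {
  p <- field_values(phi); c0 <- field_values(C0)
  if (!identical(dim(p), dim(c0))) stop("shape mismatch between phi and C0")
  scalar_field(eps * c0 * (p^2 - 1), "B_phi")
}

#' Right-hand side of the governing dynamics
#'
#' Conserved grouping (default):
#' `dphi/dt = M lap(-phi + phi^3 - eps^2 lap phi + 2 phi eps C0 B_phi -
#' eps^2 lap B_phi)`; the additive alternative moves the environment terms
#' outside the outer Laplacian, as the governing equation prints them. All
#' Laplacians use the five-point stencil with mirror closure.
#'
#' @param phi,C0 matrices or [scalar_field()]s on the same grid.
#' @param params a [model_params()].
#' @param dx lattice spacing.
#' @return matrix of time derivatives.
#' @export
rhs <- function(phi, C0, params = model_params(), dx = 1) {
  p <- field_values(phi); c0 <- field_values(C0)
  if (!identical(dim(p), dim(c0))) stop("phi and C0 must share a grid")
  out <- cpp_rhs(p, c0, params$M, params$eps, dx,
                 params$env_grouping == "conserved")
  if (any(!is.finite(out)))
    stop("non-finite right-hand side: numerical instability")
  out
}

#' Impose Dirichlet reservoir values
#' @param phi matrix or [scalar_field()].
#' @param res a [reservoir_spec()] or NULL (identity).
#' @return phi with masked sites pinned.
#' @export
apply_reservoir <- function(phi, res) {
  v <- field_values(phi)
  if (is.null(res)) return(v)
  fl <- .res_flat(res, dim(v))
  v[fl$idx + 1L] <- fl$val
  v
}

#' Advance the phase state by one Euler step
#'
#' @param state a [phase_state()].
#' @param env an `ecm_environment` (see [compose_environment()]).
#' @param params a [model_params()].
#' @param res optional [reservoir_spec()].
#' @param dx lattice spacing.
#' @return the advanced [phase_state()].
#' @export
step_phase <- function(state, env, params = model_params(), res = NULL, dx = 1) {
  fl <- .res_flat(res, dim(field_values(state$phi)))
  out <- cpp_run_steps(field_values(state$phi), field_values(env$C0),
                       params$M, params$eps, params$dt, dx, 1L,
                       fl$idx, fl$val,
                       params$env_grouping == "conserved",
                       params$overshoot_delta, 1L)
  if (!out$ok)
    stop(sprintf("instability at step %d: max |phi| = %.3g",
                 state$step_index + out$steps_done, out$max_abs_phi))
  phase_state(out$phi, state$t_insilico + params$dt, state$step_index + 1L)
}

#' Discrete Ginzburg-Landau free energy
#'
#' `F = sum(-phi^2/2 + phi^4/4 + (eps^2/2) |grad phi|^2) * dx^2` with
#' centered-difference gradients (one-sided at the boundary). With the
#' environment off the dynamics is a conserved gradient flow of F, so F is
#' non-increasing along trajectories.
#'
#' @param phi matrix or [scalar_field()].
#' @param eps interface width parameter.
#' @param dx lattice spacing.
#' @return scalar free energy.
#' @export
free_energy <- function(phi, eps = 1, dx = 1) {
  p <- field_values(phi)
  nx <- nrow(p); ny <- ncol(p)
  gx <- (p[c(2:nx, nx), ] - p[c(1, 1:(nx - 1)), ]) /
    (outer(c(1, rep(2, nx - 2), 1), rep(1, ny)) * dx)
  gy <- (p[, c(2:ny, ny)] - p[, c(1, 1:(ny - 1))]) /
    (outer(rep(1, nx), c(1, rep(2, ny - 2), 1)) * dx)
  sum(-p^2 / 2 + p^4 / 4 + (eps^2 / 2) * (gx^2 + gy^2)) * dx^2
}
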