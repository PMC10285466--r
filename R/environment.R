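#' Compose the cell-environment landscape C0
#'
#' The composite total angiogenic factor is `C0 = max(nu_c + nu_ECM, floor)`
#' with `nu_ECM = -gamma * h`: the chemoattractant activates advancement, the
#' matrix density penalizes it, and the clamp keeps `C0` at or above `floor`
#' (default 0, where cells are immobile). With the default `gamma = 0.5`
#' and the canonical [0.3, 0.5] gradient, fully dense hydrogel (h = 1) maps
#' to the immobile hydrogel band and open pores to the chemoattractant band.
#'
#' @param nu_c chemoattractant [scalar_field()].
#' @param h hydrogel density [scalar_field()], values in [0, 1].
#' @param gamma ECM coupling strength (> 0).
#' @param floor lower clamp for C0.
#' @param grid optional [grid_spec()] carried along for downstream metrics.
#' @return an object of class `ecm_environment` with elements `hydrogel`,
#'   `nu_c`, `gamma`, `floor`, `C0`, `bands`, `grid`.
#' @export
compose_environment <- function(nu_c, h, gamma = 0.5, floor = 0, grid = NULL) {
  vn <- field_values(nu_c); vh <- field_values(h)
  if (!identical(dim(vn), dim(vh))) stop("shape mismatch between nu_c and hydrogel")
  stopifnot(gamma > 0)
  C0 <- pmax(vn - gamma * vh, floor)
  env <- structure(list(hydrogel = scalar_field(vh, "hydrogel_density"),
                        nu_c = scalar_field(vn, "nu_c"),
                        gamma = gamma, floor = floor,
                        C0 = scalar_field(C0, "C0"),
                        bands = classify_bands(C0),
                        grid = grid),
                   class = "ecm_environment")
  env
}

# Rebuild C0/bands after the hydrogel has been mutated (degradation).
.recompose_C0 <- function(env) {
  C0 <- pmax(field_values(env$nu_c) - env$gamma * field_values(env$hydrogel),
             env$floor)
  env$C0 <- scalar_field(C0, "C0")
  env$bands <- classify_bands(C0)
  env
}

#' Classify C0 values into environment bands
#'
#' Half-open bands: `[0, 0.1)` hydrogel (immobile), `[0.1, 0.2)`
#' hydrogel-pore interface, `[0.2, 0.5]` pore with chemotactic factors.
#' Values below 0 (possible with a negative clamp floor) are classed as
#' hydrogel; values above 0.5 are rejected.
#'
#' @param C0 a [scalar_field()] or matrix of composite values.
#' @return a character matrix with entries `"hydrogel"`, `"interface"`,
#'   `"chemo_pore"`.
#' @export
classify_bands <- function(C0) {
  v <- field_values(C0)
  if (any(!is.finite(v))) stop("non-finite C0")
  if (any(v > 0.5 + 1e-12)) stop("C0 exceeds 0.5: invalid composition")
  b <- matrix("hydrogel", nrow(v), ncol(v))
  b[v >= 0.1 & v < 0.2] <- "interface"
  b[v >= 0.2] <- "chemo_pore"
  b
}

#' @export
print.ecm_environment <- function(x, ...) {
  tab <- table(factor(x$bands, c("hydrogel", "interface", "chemo_pore")))
  cat(sprintf("<ecm_environment> %d x %d, gamma = %g, floor = %g\n",
              nrow(x$C0), ncol(x$C0), x$gamma, x$floor))
  cat(sprintf("  bands: hydrogel %d | interface %d | chemo_pore %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}
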