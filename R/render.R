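#' Render a snapshot to an image
#'
#' Visual conventions: chemoattractant as a green-to-yellow background,
#' hydrogel as a purple overlay, cells (phi >= 0) filled red or drawn as the
#' red phi = 0 perimeter contour.
#'
#' @param state a [phase_state()] or phi matrix.
#' @param env an `ecm_environment`.
#' @param file output path.
#' @param style `"fill"` (solid red cells) or `"perimeter"` (red outline).
#' @param format `"png"` (grDevices device) or `"ppm"` (plain-text P3,
#'   byte-deterministic).
#' @param scale integer pixel magnification for PNG output.
#' @return `file`, invisibly.
#' @export
render_snapshot <- function(state, env, file, style = c("fill", "perimeter"),
                            format = c("png", "ppm"), scale = 2L) {
  style <- match.arg(style)
  format <- match.arg(format)
  phi <- if (inherits(state, "phase_state")) field_values(state$phi)
         else field_values(state)
  rgb_arr <- .snapshot_rgb(phi, env, style)
  if (format == "ppm") {
    .write_ppm(rgb_arr, file)
  } else {
    nx <- dim(rgb_arr)[1]; ny <- dim(rgb_arr)[2]
    # raster rows run top-to-bottom = decreasing y
    ras <- aperm(rgb_arr[, ny:1, , drop = FALSE], c(2, 1, 3))
    grDevices::png(file, width = nx * scale, height = ny * scale)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(ras), 0, 0, 1, 1,
                          interpolate = FALSE)
    grDevices::dev.off()
  }
  invisible(file)
}

.snapshot_rgb <- function(phi, env, style) {
  nu <- field_values(env$nu_c)
  h <- field_values(env$hydrogel)
  nx <- nrow(phi); ny <- ncol(phi)
  t_ <- pmin(nu / 0.5, 1)
  R <- 0.15 + 0.75 * t_
  G <- 0.55 + 0.40 * t_
  B <- 0.15 + 0.05 * t_
  a <- pmin(pmax(h, 0), 1) * 0.85
  R <- (1 - a) * R + a * 0.45
  G <- (1 - a) * G + a * 0.15
  B <- (1 - a) * B + a * 0.55
  cells <- phi >= 0
  mark <- if (style == "fill") cells else .perimeter(cells)
  R[mark] <- 0.85; G[mark] <- 0.08; B[mark] <- 0.08
  if (style == "fill") {
    med <- !cells & (phi < -0.999) & (h < 0.01)  # pure medium tinted blue
    B[med] <- pmin(B[med] + 0.2, 1)
  }
  arr <- array(0, c(nx, ny, 3))
  arr[, , 1] <- R; arr[, , 2] <- G; arr[, , 3] <- B
  arr
}

.perimeter <- function(cells) {
  nx <- nrow(cells); ny <- ncol(cells)
  nb <- cells[c(1, 1:(nx - 1)), ] & cells[c(2:nx, nx), ] &
        cells[, c(1, 1:(ny - 1))] & cells[, c(2:ny, ny)]
  cells & !nb
}

.write_ppm <- function(arr, file) {
  nx <- dim(arr)[1]; ny <- dim(arr)[2]
  px <- round(255 * pmin(pmax(arr, 0), 1))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(nx, ny), "255"), con)
  # rows top-to-bottom = decreasing y, columns = x
  for (j in ny:1) {
    line <- as.vector(rbind(px[, j, 1], px[, j, 2], px[, j, 3]))
    writeLines(paste(line, collapse = " "), con)
  }
  invisible(file)
}
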