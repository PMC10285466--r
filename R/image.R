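#' Load a hydrogel density field from an image or matrix file
#'
#' Reads a grayscale raster, converts to luminance if RGB, min-max normalizes
#' to [0, 1] (1 = densest hydrogel) and resamples to the simulation grid by
#' exact area-averaging. Supported inputs in this build: portable anymap text
#' images (PBM `P1`, PGM `P2`, PPM `P3`) and plain numeric matrices in
#' CSV/TSV. Normalization uses the observed min/max, not the bit depth, so
#' output is invariant to affine rescaling of the input intensities.
#'
#' A constant (zero-dynamic-range) input carries no structure: a warning is
#' issued and an all-zero field is returned.
#'
#' @param path file path (`.pbm`, `.pgm`, `.ppm`, `.csv`, `.tsv`, `.txt`).
#' @param grid a [grid_spec()] giving the target shape.
#' @return a [scalar_field()] with role `hydrogel_density`.
#' @export
load_hydrogel_image <- function(path, grid) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pbm = , pgm = , ppm = .read_pnm(path),
    csv = as.matrix(read.table(path, sep = ",", header = FALSE)),
    tsv = , txt = as.matrix(read.table(path, header = FALSE)),
    stop(sprintf("unsupported image format '.%s'", ext)))
  storage.mode(img) <- "double"
  if (!all(is.finite(img))) stop("non-finite pixel values in image")
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("zero-dynamic-range image: returning constant all-zero field")
    img[] <- 0
  } else {
    img <- (img - rng[1]) / diff(rng)
  }
  scalar_field(.area_resample(img, grid$nx, grid$ny), "hydrogel_density", grid)
}

# Tokenized reader for plain (ASCII) netpbm. Returns a matrix with rows = x,
# cols = y; RGB (P3) is collapsed by Rec. 709 luminance.
.read_pnm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- scan(text = paste(lines, collapse = " "), what = character(),
               quiet = TRUE)
  magic <- toks[1]
  if (!magic %in% c("P1", "P2", "P3"))
    stop(sprintf("unsupported netpbm magic '%s' (plain P1/P2/P3 only)", magic))
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  if (magic == "P1") {
    vals <- as.numeric(toks[-(1:3)])
    px <- 1 - vals  # PBM: 1 = black
    ch <- 1L
  } else {
    maxval <- as.numeric(toks[4])
    vals <- as.numeric(toks[-(1:4)]) / maxval
    ch <- if (magic == "P3") 3L else 1L
    px <- vals
  }
  if (length(px) != w * h * ch) stop("truncated netpbm payload")
  if (ch == 3L) {
    r <- px[seq(1, length(px), 3)]
    g <- px[seq(2, length(px), 3)]
    b <- px[seq(3, length(px), 3)]
    px <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  }
  # netpbm stores row-major, top row first: element (row r, col c) at
  # (r-1)*w + c. Map image columns -> x, image rows -> y.
  m <- matrix(px, nrow = w, ncol = h)  # m[c, r]
  m
}

# Exact area-weighted resampling of an n1 x n2 matrix to nx x ny.
.area_resample <- function(img, nx, ny) {
  wmat <- function(n_from, n_to) {
    # overlap length of source cell s = [s-1, s] with target cell
    # t = [(t-1)*n_from/n_to, t*n_from/n_to], normalized to target width
    w <- matrix(0, n_to, n_from)
    scale <- n_from / n_to
    for (t in seq_len(n_to)) {
      lo <- (t - 1) * scale; hi <- t * scale
      s0 <- floor(lo) + 1; s1 <- ceiling(hi)
      for (s in s0:min(s1, n_from)) {
        ov <- min(hi, s) - max(lo, s - 1)
        if (ov > 0) w[t, s] <- ov / scale
      }
    }
    w
  }
  wx <- wmat(nrow(img), nx)
  wy <- wmat(ncol(img), ny)
  wx %*% img %*% t(wy)
}
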