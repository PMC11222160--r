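#' 2D image with physical sampling
#'
#' Light container for a 2D pixel raster. Data are stored as a numeric
#' matrix (`nrow` = ny, `ncol` = nx) with the physical pixel size attached.
#' The physical frame has its origin at the geometric centre of the raster,
#' x to the right and y up, in ångström; row 1 is the top of the image.
#'
#' @param data numeric matrix of pixel values.
#' @param pixel_size pixel size in Å per pixel (isotropic).
#' @return An object of class `mem_image`.
#' @export
mem_image <- function(data, pixel_size) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (Å/px)")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "mem_image")
}

#' 3D volume with physical sampling
#'
#' @param data numeric 3D array, indexed `[ix, iy, iz]`.
#' @param voxel_size voxel size in Å (isotropic).
#' @return An object of class `mem_volume`.
#' @export
mem_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (Å)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "mem_volume")
}

#' @export
print.mem_image <- function(x, ...) {
  cat(sprintf("<mem_image %d x %d px, %.4g Å/px, range [%.4g, %.4g]>\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mem_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mem_volume %d x %d x %d vx, %.4g Å/vx>\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' @export
dim.mem_image <- function(x) dim(x$data)

#' @export
dim.mem_volume <- function(x) dim(x$data)

# Physical coordinates (Å, centre origin, y up) of every pixel.
# Returns list(x = matrix, y = matrix) matching the raster layout.
pixel_grid <- function(shape, pixel_size) {
  ny <- shape[1]; nx <- shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- (seq_len(nx) - cx) * pixel_size
  ys <- (cy - seq_len(ny)) * pixel_size
  list(x = matrix(xs, ny, nx, byrow = TRUE),
       y = matrix(ys, ny, nx, byrow = FALSE))
}

# Physical (x, y) -> fractional raster indices (row, col).
xy_to_rc <- function(x, y, shape, pixel_size) {
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  list(row = cy - y / pixel_size, col = x / pixel_size + cx)
}

# Fractional raster indices -> physical (x, y).
rc_to_xy <- function(row, col, shape, pixel_size) {
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  list(x = (col - cx) * pixel_size, y = (cy - row) * pixel_size)
}

#' Bilinear interpolation of an image at physical coordinates
#'
#' Samples pixel values at arbitrary physical positions (Å, centre-origin
#' frame) by bilinear interpolation; positions outside the raster return
#' `fill`.
#'
#' @param img a [mem_image()].
#' @param x,y numeric vectors of physical coordinates in Å.
#' @param fill value returned outside the raster (default 0).
#' @return numeric vector of interpolated values.
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  m <- img$data
  rc <- xy_to_rc(x, y, dim(m), img$pixel_size)
  r <- rc$row; c <- rc$col
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ny <- nrow(m); nx <- ncol(m)
  inside <- r0 >= 1 & r0 <= ny - 1 & c0 >= 1 & c0 <= nx - 1
  out <- rep(fill, length(x))
  if (any(inside)) {
    r0i <- r0[inside]; c0i <- c0[inside]
    fri <- fr[inside]; fci <- fc[inside]
    i00 <- (c0i - 1) * ny + r0i           # linear index of [r0, c0]
    v <- (1 - fri) * (1 - fci) * m[i00] +
         fri       * (1 - fci) * m[i00 + 1] +
         (1 - fri) * fci       * m[i00 + ny] +
         fri       * fci       * m[i00 + ny + 1]
    out[inside] <- v
  }
  out
}

#' Catmull-Rom bicubic interpolation of an image at physical coordinates
#'
#' Higher-order counterpart of [bilinear_sample()], used where resampling
#' fidelity matters (membrane-signal estimation). Positions whose 4x4
#' support leaves the raster fall back to bilinear/fill behaviour.
#'
#' @inheritParams bilinear_sample
#' @return numeric vector of interpolated values.
#' @export
cubic_sample <- function(img, x, y, fill = 0) {
  m <- img$data
  ny <- nrow(m); nx <- ncol(m)
  rc <- xy_to_rc(x, y, dim(m), img$pixel_size)
  r0 <- floor(rc$row); c0 <- floor(rc$col)
  inner <- r0 >= 2 & r0 <= ny - 2 & c0 >= 2 & c0 <= nx - 2
  out <- bilinear_sample(img, x, y, fill)
  if (!any(inner)) return(out)
  tr <- rc$row[inner] - r0[inner]
  tc <- rc$col[inner] - c0[inner]
  wgt <- function(t, k) {  # Catmull-Rom weights, k in -1..2
    switch(as.character(k),
      "-1" = 0.5 * (-t + 2 * t^2 - t^3),
      "0"  = 0.5 * (2 - 5 * t^2 + 3 * t^3),
      "1"  = 0.5 * (t + 4 * t^2 - 3 * t^3),
      "2"  = 0.5 * (-t^2 + t^3))
  }
  acc <- numeric(sum(inner))
  r0i <- r0[inner]; c0i <- c0[inner]
  for (kr in -1:2) {
    wr <- wgt(tr, kr)
    for (kc in -1:2) {
      wc <- wgt(tc, kc)
      acc <- acc + wr * wc * m[(c0i + kc - 1) * ny + (r0i + kr)]
    }
  }
  out[inner] <- acc
  out
}

#' Rotate an image about its centre
#'
#' Rotates the image content counter-clockwise (in the physical x-right /
#' y-up frame) by `angle` degrees, output on the same raster, bilinear
#' resampling, zero fill.
#'
#' @param img a [mem_image()].
#' @param angle rotation in degrees, counter-clockwise.
#' @return a [mem_image()] of the same shape.
#' @export
rotate_image <- function(img, angle) {
  if (angle %% 360 == 0) return(img)
  g <- pixel_grid(dim(img$data), img$pixel_size)
  a <- angle * pi / 180
  # output(x, y) samples input at the inverse rotation
  xs <- cos(a) * g$x + sin(a) * g$y
  ys <- -sin(a) * g$x + cos(a) * g$y
  v <- bilinear_sample(img, as.vector(xs), as.vector(ys))
  mem_image(matrix(v, nrow(img$data), ncol(img$data)), img$pixel_size)
}

# 2D FFT-based circular cross-correlation.
# Entry [i, j] is sum_{r,c} a[r, c] * b[r - (i-1), c - (j-1)] with wraparound:
# i.e. the correlation of a with b shifted DOWN by (i-1) rows and RIGHT by
# (j-1) columns. Shift (0, 0) is at [1, 1].
cross_correlate <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a)
}

# Convert the [1..n] circular-shift index to a signed shift in [-n/2, n/2).
signed_shift <- function(idx, n) {
  s <- idx - 1L
  ifelse(s > n / 2, s - n, s)
}

# Parabolic (three-point) interpolation of an extremum position.
# y1, y2, y3 at x = -1, 0, 1 with y2 the discrete extremum; returns the
# sub-grid offset in (-0.5, 0.5) and the interpolated peak value.
parabolic_peak <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * (abs(y2) + 1)) {
    return(list(offset = 0, value = y2))
  }
  off <- 0.5 * (y1 - y3) / denom
  off <- max(-0.5, min(0.5, off))
  list(offset = off, value = y2 - 0.25 * (y1 - y3) * off)
}
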