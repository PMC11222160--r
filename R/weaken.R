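#' Configuration of membrane-signal estimation and weakening
#'
#' @param mask_scale ratio of the soft-mask plateau width to the bilayer
#'   thickness (default 1.25, i.e. a mask about 25% larger than the
#'   bilayer).
#' @param soft_edge cosine edge width of the mask, Å (default 10; 0 gives a
#'   binary mask).
#' @param along_window running-average window along the membrane curve, Å
#'   (default 150).
#' @param lambda weakening weight in `[0, 1]` (default 0.7; 1 subtracts the
#'   full estimated membrane signal).
#' @return An object of class `weaken_config`.
#' @export
weaken_config <- function(mask_scale = 1.25, soft_edge = 10,
                          along_window = 150, lambda = 0.7) {
  if (mask_scale < 1) stop("mask_scale must be >= 1")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (soft_edge < 0) stop("soft_edge must be >= 0")
  if (along_window <= 0) stop("along_window must be positive")
  structure(list(mask_scale = mask_scale, soft_edge = soft_edge,
                 along_window = along_window, lambda = lambda),
            class = "weaken_config")
}

# Cosine-edged band profile: 1 on [0, plateau], cosine falloff over edge.
soft_band <- function(d, plateau, edge) {
  out <- numeric(length(d))
  out[d <= plateau] <- 1
  if (edge > 0) {
    sel <- d > plateau & d < plateau + edge
    out[sel] <- 0.5 * (1 + cos(pi * (d[sel] - plateau) / edge))
  }
  out
}

#' Soft mask around a membrane curve
#'
#' Value 1 within a normal distance of `mask_scale * thickness / 2` of the
#' arc, cosine falloff over `soft_edge`, 0 outside; the arc ends are capped
#' with the same falloff.
#'
#' @param curve an [arc_segment()].
#' @param shape raster shape, `c(ny, nx)` pixels.
#' @param pixel_size Å per pixel.
#' @param cfg a [weaken_config()].
#' @return a [mem_image()] with values in `[0, 1]`.
#' @export
curve_mask <- function(curve, shape, pixel_size, cfg = weaken_config()) {
  g <- pixel_grid(shape, pixel_size)
  cs <- arc_coords(as.vector(g$x), as.vector(g$y), curve)
  half_w <- cfg$mask_scale * curve$thickness / 2
  # the normal-direction plateau is mask_scale * thickness wide; the
  # end caps roll off INSIDE the arc, reaching zero at the terminus, where
  # the finite segment makes the membrane estimate unreliable
  m <- soft_band(abs(cs$n), half_w, cfg$soft_edge) *
       soft_band(abs(cs$s), pmax(curve$length / 2 - cfg$soft_edge, 0),
                 cfg$soft_edge)
  mem_image(matrix(m, shape[1], shape[2]), pixel_size)
}

#' Estimate the principal membrane signal along a fitted curve
#'
#' Resamples the image into curvilinear membrane coordinates (arc length s,
#' normal offset n) on an oversampled grid (Catmull-Rom interpolation),
#' applies a running average along s with window `along_window` at each
#' fixed n, resamples back to the raster frame and multiplies by the soft
#' [curve_mask()]. The result is exactly zero outside the mask support.
#'
#' @param image a [mem_image()].
#' @param curve the [arc_segment()] fitted to this image's membrane.
#' @param cfg a [weaken_config()].
#' @return a [mem_image()]: the membrane-signal estimate.
#' @export
estimate_membrane_signal <- function(image, curve, cfg = weaken_config()) {
  stopifnot(inherits(image, "mem_image"), inherits(curve, "arc_segment"))
  px <- image$pixel_size
  W <- cfg$along_window
  if (W > curve$length) {
    warning("along_window larger than the curve; clamped to the curve length")
    W <- curve$length
  }
  half_w <- cfg$mask_scale * curve$thickness / 2 + cfg$soft_edge
  # the s grid stops at the membrane ends: averaging across the terminus
  # would mix in empty background; beyond-end pixels (under the soft cap)
  # read the end value of the running average instead
  half_l <- curve$length / 2
  # the (s, n) grid oversamples the raster (s: half-pixel, n: quarter-pixel)
  # so that the back-interpolation of the sharp head-band profile stays well
  # below the band amplitude
  ds <- px / 2
  dn <- px / 4
  s_ax <- seq(-half_l, half_l, by = ds)
  n_ax <- seq(-half_w, half_w, by = dn)
  p <- arc_point(curve, rep(s_ax, times = length(n_ax)),
                 rep(n_ax, each = length(s_ax)))
  samp <- matrix(cubic_sample(image, p$x, p$y),
                 length(s_ax), length(n_ax))
  # edge-normalized running average along s at each n
  w_px <- max(1L, round(W / ds))
  if (w_px %% 2 == 0) w_px <- w_px + 1L
  kern <- rep(1, w_px)
  sm <- apply(samp, 2, function(col) {
    num <- stats::filter(col, kern, sides = 2)
    den <- stats::filter(rep(1, length(col)), kern, sides = 2)
    as.numeric(num / den)
  })
  # filter() leaves NA at the ends shorter than the half window
  half_k <- (w_px - 1) / 2
  if (half_k > 0) {
    for (j in seq_len(ncol(sm))) {
      col <- samp[, j]
      for (i in seq_len(half_k)) {
        sm[i, j] <- mean(col[1:min(i + half_k, length(col))])
        ii <- length(col) - i + 1
        sm[ii, j] <- mean(col[max(1, ii - half_k):length(col)])
      }
    }
  }
  # resample back: each raster pixel inside the mask support reads the
  # smoothed (s, n) field bilinearly
  mask <- curve_mask(curve, dim(image$data), px, cfg)
  out <- matrix(0, nrow(image$data), ncol(image$data))
  sel <- which(mask$data > 0)
  if (length(sel)) {
    g <- pixel_grid(dim(image$data), px)
    cs <- arc_coords(g$x[sel], g$y[sel], curve)
    si <- (cs$s + half_l) / ds + 1
    ni <- (cs$n + half_w) / dn + 1
    s0 <- pmin(pmax(floor(si), 1), length(s_ax) - 1)
    n0 <- pmin(pmax(floor(ni), 1), length(n_ax) - 1)
    fs <- pmin(pmax(si - s0, 0), 1); fn <- pmin(pmax(ni - n0, 0), 1)
    nsr <- nrow(sm)
    i00 <- (n0 - 1) * nsr + s0
    v <- (1 - fs) * (1 - fn) * sm[i00] +
         fs       * (1 - fn) * sm[i00 + 1] +
         (1 - fs) * fn       * sm[i00 + nsr] +
         fs       * fn       * sm[i00 + nsr + 1]
    out[sel] <- v * mask$data[sel]
  }
  mem_image(out, px)
}

#' Weaken the membrane signal of an image
#'
#' Subtracts `lambda` times the membrane-signal estimate. Pixels where the
#' estimate is exactly zero (outside the mask support) are bit-identical to
#' the input.
#'
#' @param image a [mem_image()].
#' @param membrane_est a [mem_image()] from [estimate_membrane_signal()],
#'   same shape.
#' @param lambda weakening weight in `[0, 1]`.
#' @return a [mem_image()].
#' @export
weaken_membrane <- function(image, membrane_est, lambda = 0.7) {
  stopifnot(inherits(image, "mem_image"), inherits(membrane_est, "mem_image"))
  if (!all(dim(image$data) == dim(membrane_est$data)))
    stop("image and membrane estimate shapes differ")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  mem_image(image$data - lambda * membrane_est$data, image$pixel_size)
}
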