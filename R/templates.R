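#' Bilayer cross-section density profile specification
#'
#' Parameterizes the 1D density profile of a lipid bilayer seen edge-on as a
#' function of the offset from the bilayer mid-plane: two Gaussian headgroup
#' bands centred at +/- t/2 plus a lower, flat-topped tail plateau around the
#' mid-plane. The profile is an even function of the offset. Densities are
#' signal-positive (membrane bright); sign conventions at I/O are handled by
#' the writers.
#'
#' @param thickness head-to-head distance t, Å (default 40, i.e. the ~4 nm
#'   bilayer of mitochondrial inner membranes).
#' @param head_sigma Gaussian width of each headgroup band, Å.
#' @param head_amp peak amplitude of each headgroup band (density units).
#' @param tail_amp amplitude of the tail plateau (density units, < head_amp).
#' @param tail_sigma half-width scale of the tail plateau, Å.
#' @return An object of class `bilayer_profile_spec`.
#' @export
bilayer_profile_spec <- function(thickness = 40, head_sigma = 5,
                                 head_amp = 1.0, tail_amp = 0.35,
                                 tail_sigma = 8) {
  if (thickness <= 0) stop("thickness must be positive")
  if (head_amp < 0 || tail_amp < 0) stop("amplitudes must be non-negative")
  if (head_sigma <= 0 || tail_sigma <= 0) stop("sigmas must be positive")
  structure(list(thickness = thickness, head_sigma = head_sigma,
                 head_amp = head_amp, tail_amp = tail_amp,
                 tail_sigma = tail_sigma),
            class = "bilayer_profile_spec")
}

#' Evaluate the bilayer density profile
#'
#' @param spec a [bilayer_profile_spec()].
#' @param n normal offset(s) from the bilayer mid-plane, Å.
#' @return density value(s); even in `n`, decaying to 0 away from the
#'   bilayer.
#' @export
bilayer_profile <- function(spec, n) {
  t2 <- spec$thickness / 2
  heads <- spec$head_amp * (exp(-(n - t2)^2 / (2 * spec$head_sigma^2)) +
                            exp(-(n + t2)^2 / (2 * spec$head_sigma^2)))
  # flat-topped (4th-order super-Gaussian) tail plateau
  tail <- spec$tail_amp * exp(-0.5 * (n / spec$tail_sigma)^4)
  heads + tail
}

# Normal half-extent beyond which the profile is numerically negligible.
profile_support <- function(spec) {
  spec$thickness / 2 + 5 * max(spec$head_sigma, spec$tail_sigma)
}

#' Render a 2D projection of a curved bilayer
#'
#' Renders the bilayer profile along a circular arc of signed curvature
#' `kappa` passing through the image centre with a horizontal tangent there.
#' `kappa = 0` gives a straight horizontal band; `kappa > 0` bends the
#' membrane towards +y (image "up").
#'
#' @param kappa signed curvature, nm^-1.
#' @param length arc length, Å.
#' @param image_size output raster size in pixels (square).
#' @param pixel_size Å per pixel.
#' @param spec a [bilayer_profile_spec()].
#' @return a [mem_image()].
#' @export
simulate_bilayer_projection <- function(kappa, length, image_size, pixel_size,
                                        spec = bilayer_profile_spec()) {
  curve <- arc_segment(centre = c(0, 0), theta = 0, kappa = kappa,
                       length = length, thickness = spec$thickness)
  frame_A <- image_size * pixel_size
  ext <- arc_extent(curve, spec)
  if (any(abs(ext) > frame_A / 2))
    stop(sprintf("arc (kappa=%.4g nm^-1, length=%.4g Å) leaves the %g Å frame",
                 kappa, length, frame_A))
  render_arc(curve, c(image_size, image_size), pixel_size, spec)
}

# Bounding half-extents (x, y) in Å of a rendered arc, profile included.
arc_extent <- function(curve, spec) {
  s <- seq(-curve$length / 2, curve$length / 2, length.out = 65)
  sup <- profile_support(spec)
  p1 <- arc_point(curve, s, rep(sup, length(s)))
  p2 <- arc_point(curve, s, rep(-sup, length(s)))
  c(max(abs(c(p1$x, p2$x))), max(abs(c(p1$y, p2$y))))
}

# Render the profile of `curve` into a raster (shape = c(ny, nx)).
# Each pixel value approximates the mean density over the pixel area
# (oversample^2-point quadrature), which keeps the rendered integral
# independent of curvature and pixel phase.
render_arc <- function(curve, shape, pixel_size, spec, oversample = 3L) {
  g <- pixel_grid(shape, pixel_size)
  sup <- profile_support(spec)
  offs <- (seq_len(oversample) - (oversample + 1) / 2) / oversample * pixel_size
  acc <- numeric(length(g$x))
  for (ox in offs) for (oy in offs) {
    cs <- arc_coords(as.vector(g$x) + ox, as.vector(g$y) + oy, curve)
    sel <- abs(cs$n) <= sup & abs(cs$s) <= curve$length / 2
    if (any(sel)) acc[sel] <- acc[sel] + bilayer_profile(spec, cs$n[sel])
  }
  mem_image(matrix(acc / oversample^2, shape[1], shape[2]), pixel_size)
}

#' Build a curvature-indexed bank of simulated bilayer templates
#'
#' Generates an ordered series of simulated 2D bilayer projections with local
#' curvature evenly spaced from `kappa_min` to `kappa_max` (endpoints
#' included), for use as matched-filter templates for membrane side-view
#' detection and for curvature estimation by cross-correlation.
#'
#' @param kappa_min,kappa_max curvature range, nm^-1 (defaults 0 and 0.02).
#' @param n_templates number of templates (>= 2; typically 15-30).
#' @param length arc length of each template, Å.
#' @param image_size template raster size in pixels (square).
#' @param pixel_size Å per pixel.
#' @param spec a [bilayer_profile_spec()].
#' @return An object of class `template_bank`: list with `kappas` (nm^-1),
#'   `images` (list of [mem_image()]), `pixel_size`, `length`, `spec`.
#' @export
make_template_bank <- function(kappa_min = 0, kappa_max = 0.02,
                               n_templates = 21, length = 300,
                               image_size = 96, pixel_size = 4,
                               spec = bilayer_profile_spec()) {
  if (kappa_max < kappa_min) stop("kappa_max must be >= kappa_min")
  if (n_templates < 2) stop("n_templates must be >= 2")
  kappas <- seq(kappa_min, kappa_max, length.out = n_templates)
  images <- lapply(kappas, simulate_bilayer_projection, length = length,
                   image_size = image_size, pixel_size = pixel_size,
                   spec = spec)
  structure(list(kappas = kappas, images = images, pixel_size = pixel_size,
                 length = length, spec = spec),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(
    "<template_bank %d templates, kappa %.4g..%.4g nm^-1, %d px @ %.3g Å/px>\n",
    length(x$kappas), min(x$kappas), max(x$kappas),
    nrow(x$images[[1]]$data), x$pixel_size))
  invisible(x)
}
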