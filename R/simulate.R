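# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground-truth membrane segment for a synthetic micrograph
#'
#' Same geometry as [arc_segment()]; kept as its own constructor so that
#' generator ground truth validates the simulation-specific invariants
#' (curvature within the physiological range, bilayer thickness 30-60 Å).
#'
#' @inheritParams arc_segment
#' @return an [arc_segment()] (ground truth is stored in the same class the
#'   estimators consume).
#' @export
ground_truth_segment <- function(centre = c(0, 0), theta = 0, kappa = 0,
                                 length = 300, thickness = 40) {
  if (abs(kappa) > 0.05)
    stop("|kappa| must be <= 0.05 nm^-1 for a synthetic membrane segment")
  if (thickness < 30 || thickness > 60)
    stop("thickness must be in [30, 60] Å")
  arc_segment(centre, theta, kappa, length, thickness)
}

#' Specification of a synthetic 2D micrograph
#'
#' Describes a simulated cryo-EM micrograph scene: bilayer side-view
#' segments rendered with the standard bilayer profile, globular "protein"
#' blobs, and additive white Gaussian noise scaled to a target
#' signal-to-noise ratio (variance of the noise-free scene divided by the
#' noise variance). Contrast is density-positive internally; `em_dark`
#' inverts the sign to mimic raw cryo-EM contrast at output.
#'
#' @param image_size raster size in pixels (square, >= 64).
#' @param pixel_size Å per pixel.
#' @param segments list of [ground_truth_segment()]s.
#' @param n_blobs number of globular densities.
#' @param blob_sigma Gaussian sigma of each blob, Å.
#' @param blob_amp peak amplitude of each blob (density units).
#' @param snr target signal-to-noise ratio (> 0; ignored if
#'   `noise_model = "none"`).
#' @param noise_model `"gaussian"` or `"none"`.
#' @param contrast `"density_positive"` (default) or `"em_dark"`.
#' @param profile [bilayer_profile_spec()] used to render the segments.
#' @param seed integer RNG seed.
#' @return An object of class `sim_spec_2d`.
#' @export
sim_spec_2d <- function(image_size = 256, pixel_size = 4, segments = list(),
                        n_blobs = 0, blob_sigma = 20, blob_amp = 1,
                        snr = 0.5, noise_model = c("gaussian", "none"),
                        contrast = c("density_positive", "em_dark"),
                        profile = bilayer_profile_spec(), seed = 1) {
  noise_model <- match.arg(noise_model)
  contrast <- match.arg(contrast)
  if (image_size < 64) stop("image_size must be >= 64")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (noise_model != "none" && snr <= 0) stop("snr must be positive")
  stopifnot(all(vapply(segments, inherits, TRUE, "arc_segment")))
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, segments = segments,
                 n_blobs = as.integer(n_blobs), blob_sigma = blob_sigma,
                 blob_amp = blob_amp, snr = snr, noise_model = noise_model,
                 contrast = contrast, profile = profile,
                 seed = as.integer(seed)),
            class = "sim_spec_2d")
}

#' Simulate a micrograph with membrane segments, blobs and noise
#'
#' Renders every ground-truth segment with the bilayer profile, adds
#' `n_blobs` Gaussian blobs placed uniformly at random outside a
#' one-thickness exclusion zone around the membranes, and adds white
#' Gaussian noise with variance `var(signal) / snr`. Identical spec and seed
#' give a bit-identical image. Segments whose arc leaves the frame by more
#' than 10% of their length trigger a warning and are truncated at the
#' frame.
#'
#' @param spec a [sim_spec_2d()].
#' @return list with `image` (a [mem_image()]), `segments` (the ground
#'   truth, returned verbatim) and `blobs` (data.frame of blob centres, Å).
#' @export
simulate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "sim_spec_2d"))
  shape <- c(spec$image_size, spec$image_size)
  frame_half <- spec$image_size * spec$pixel_size / 2
  signal <- matrix(0, shape[1], shape[2])
  for (seg in spec$segments) {
    ss <- seq(-seg$length / 2, seg$length / 2, length.out = 129)
    p <- arc_point(seg, ss, rep(0, length(ss)))
    outside <- mean(pmax(abs(p$x), abs(p$y)) > frame_half)
    if (outside > 0.10)
      warning(sprintf(
        "segment extends beyond the image border for %.0f%% of its length; truncated",
        100 * outside))
    signal <- signal +
      render_arc(seg, shape, spec$pixel_size, spec$profile)$data
  }
  blobs <- data.frame(x = numeric(0), y = numeric(0))
  img <- with_seed(spec$seed, {
    if (spec$n_blobs > 0) {
      blobs <- place_blobs(spec, frame_half)
      g <- pixel_grid(shape, spec$pixel_size)
      for (i in seq_len(nrow(blobs))) {
        signal <- signal + spec$blob_amp *
          exp(-((g$x - blobs$x[i])^2 + (g$y - blobs$y[i])^2) /
                (2 * spec$blob_sigma^2))
      }
    }
    out <- signal
    if (spec$noise_model == "gaussian") {
      sd_noise <- sqrt(stats::var(as.vector(signal)) / spec$snr)
      if (!is.finite(sd_noise)) sd_noise <- 0
      out <- out + matrix(stats::rnorm(length(signal), sd = sd_noise),
                          shape[1], shape[2])
    }
    out
  })
  if (spec$contrast == "em_dark") img <- -img
  list(image = mem_image(img, spec$pixel_size),
       segments = spec$segments, blobs = blobs)
}

# Uniform-random blob centres, rejecting positions within one bilayer
# thickness (normal distance) of any segment, and keeping blobs inside the
# frame by 3 sigma.
place_blobs <- function(spec, frame_half) {
  lim <- frame_half - 3 * spec$blob_sigma
  xs <- numeric(spec$n_blobs); ys <- numeric(spec$n_blobs)
  for (i in seq_len(spec$n_blobs)) {
    for (try in 1:1000) {
      x <- stats::runif(1, -lim, lim)
      y <- stats::runif(1, -lim, lim)
      ok <- TRUE
      for (seg in spec$segments) {
        cs <- arc_coords(x, y, seg)
        if (abs(cs$n) < seg$thickness + spec$blob_sigma &&
            abs(cs$s) < seg$length / 2 + seg$thickness) { ok <- FALSE; break }
      }
      if (ok) break
      if (try == 1000) stop("could not place blob outside membrane exclusion zones")
    }
    xs[i] <- x; ys[i] <- y
  }
  data.frame(x = xs, y = ys)
}

#' Specification of a synthetic 3D membrane volume
#'
#' Describes a voxel grid containing a curved bilayer slab: two parallel
#' high-density shells offset by +/- thickness/2 along the local normal of
#' an analytic mid-surface z = f(x, y) (plane, spherical cap or sinusoid),
#' optionally with an embedded transmembrane cylinder ("protein").
#'
#' @param grid_size voxels per edge (cubic grid, >= 48).
#' @param voxel_size Å per voxel.
#' @param surface_kind `"plane"`, `"sphere_cap"` or `"sinusoid"`.
#' @param surface_params named list: `z0` (plane offset, Å); `R` (sphere
#'   radius, Å; the cap is a dome, apex up at z = z0); `amplitude` and
#'   `wavelength` (sinusoid, Å).
#' @param thickness leaflet head-to-head separation, Å (default 40).
#' @param shell_sigma Gaussian width of each density shell, Å.
#' @param include_protein embed a cylinder crossing both shells.
#' @param seed integer RNG seed (reserved; the volume itself is noise-free).
#' @return An object of class `sim_spec_3d`.
#' @export
sim_spec_3d <- function(grid_size = 64, voxel_size = 4,
                        surface_kind = c("plane", "sphere_cap", "sinusoid"),
                        surface_params = list(), thickness = 40,
                        shell_sigma = 4, include_protein = FALSE, seed = 1) {
  surface_kind <- match.arg(surface_kind)
  if (grid_size < 48) stop("grid_size must be >= 48")
  if (thickness <= 0) stop("thickness must be positive")
  extent <- grid_size * voxel_size
  if (surface_kind == "sphere_cap") {
    R <- surface_params$R
    if (is.null(R)) stop("surface_params$R (sphere radius, Å) is required")
    if (R <= extent / 4)
      stop(sprintf("sphere radius R = %g Å too small for the %g Å grid (need R > extent/4)",
                   R, extent))
  }
  structure(list(grid_size = as.integer(grid_size), voxel_size = voxel_size,
                 surface_kind = surface_kind, surface_params = surface_params,
                 thickness = thickness, shell_sigma = shell_sigma,
                 include_protein = isTRUE(include_protein),
                 seed = as.integer(seed)),
            class = "sim_spec_3d")
}

# Analytic mid-surface of a sim_spec_3d as a function z = f(x, y) (Å).
surface_function <- function(spec) {
  p <- spec$surface_params
  z0 <- if (is.null(p$z0)) 0 else p$z0
  switch(spec$surface_kind,
    plane = function(x, y) rep(z0, length(x)),
    sphere_cap = {
      R <- p$R
      # dome: apex at (0, 0, z0), centre of the sphere at z0 - R
      function(x, y) {
        r2 <- x^2 + y^2
        if (any(r2 >= R^2)) stop("sphere_cap surface exits the lateral grid (R too small)")
        z0 - R + sqrt(R^2 - r2)
      }
    },
    sinusoid = {
      A <- if (is.null(p$amplitude)) 20 else p$amplitude
      lam <- if (is.null(p$wavelength)) 200 else p$wavelength
      function(x, y) z0 + A * sin(2 * pi * x / lam)
    })
}

#' Simulate a 3D volume containing a curved bilayer slab
#'
#' @param spec a [sim_spec_3d()].
#' @return list with `volume` (a [mem_volume()]), `f` (the analytic
#'   mid-surface, callable as `f(x, y)` in Å) and `spec`.
#' @export
simulate_membrane_volume <- function(spec) {
  stopifnot(inherits(spec, "sim_spec_3d"))
  n <- spec$grid_size; vs <- spec$voxel_size
  ax <- (seq_len(n) - (n + 1) / 2) * vs
  f <- surface_function(spec)
  xy_x <- matrix(ax, n, n, byrow = FALSE)
  xy_y <- matrix(ax, n, n, byrow = TRUE)
  zmid <- matrix(f(as.vector(xy_x), as.vector(xy_y)), n, n)
  zext <- max(abs(zmid)) + spec$thickness / 2 + 3 * spec$shell_sigma
  if (zext > n * vs / 2)
    stop(sprintf("surface (|z| up to %.0f Å) exits the grid: reduce amplitude/curvature or z0",
                 max(abs(zmid))))
  # normal-distance approximation via the surface gradient (Monge patch)
  eps <- vs / 2
  fx <- (matrix(f(as.vector(xy_x) + eps, as.vector(xy_y)), n, n) -
         matrix(f(as.vector(xy_x) - eps, as.vector(xy_y)), n, n)) / (2 * eps)
  fy <- (matrix(f(as.vector(xy_x), as.vector(xy_y) + eps), n, n) -
         matrix(f(as.vector(xy_x), as.vector(xy_y) - eps), n, n)) / (2 * eps)
  cosal <- 1 / sqrt(1 + fx^2 + fy^2)
  vol <- array(0, c(n, n, n))
  t2 <- spec$thickness / 2
  for (iz in seq_len(n)) {
    dn <- (ax[iz] - zmid) * cosal
    vol[, , iz] <- exp(-(dn - t2)^2 / (2 * spec$shell_sigma^2)) +
                   exp(-(dn + t2)^2 / (2 * spec$shell_sigma^2))
  }
  if (spec$include_protein) {
    r_cyl <- 15
    rad2 <- outer(ax^2, ax^2, "+")
    mask <- rad2 <= r_cyl^2
    zc <- f(0, 0)
    for (iz in seq_len(n)) {
      if (abs(ax[iz] - zc) <= t2 + 4 * spec$shell_sigma)
        vol[, , iz][mask] <- vol[, , iz][mask] + 1.5
    }
  }
  list(volume = mem_volume(vol, vs), f = f, spec = spec)
}

#' Specification of a coordinate-model fixture
#'
#' Describes a synthetic structure model: phosphorus pseudo-atoms (lipid
#' headgroups) on a jittered square lattice at a known mean height, plus a
#' single quinone-like ligand atom at a known height above the headgroup
#' plane. Used as exact ground truth for membrane-height and ligand-height
#' measurements.
#'
#' @param lattice_extent lateral half-extent of the lattice, Å.
#' @param lattice_spacing lattice spacing, Å (> 0).
#' @param head_plane_z mean z of the headgroup plane, Å.
#' @param ligand_height ligand z above the head plane, Å (may be negative).
#' @param jitter_sigma Gaussian jitter applied to headgroup z, Å (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `model_fixture_spec`.
#' @export
model_fixture_spec <- function(lattice_extent = 80, lattice_spacing = 8,
                               head_plane_z = 0, ligand_height = 20,
                               jitter_sigma = 0, seed = 1) {
  if (lattice_spacing <= 0) stop("lattice_spacing must be positive")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(lattice_extent = lattice_extent,
                 lattice_spacing = lattice_spacing,
                 head_plane_z = head_plane_z,
                 ligand_height = ligand_height,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "model_fixture_spec")
}

#' Build a synthetic coordinate model of lipid headgroups plus a ligand
#'
#' Phosphorus pseudo-atoms (atom name `P`, residue `POP`, chain `L`) sit on
#' a square lattice with optional Gaussian z jitter; one ligand atom (atom
#' name `O1`, residue `Q1C`, chain `Q`) is placed on the lattice axis at
#' `head_plane_z + ligand_height`.
#'
#' @param spec a [model_fixture_spec()].
#' @return a `mem_structure` (see [structure_model()]).
#' @export
make_fixture_model <- function(spec) {
  stopifnot(inherits(spec, "model_fixture_spec"))
  xs <- seq(-spec$lattice_extent, spec$lattice_extent,
            by = spec$lattice_spacing)
  g <- expand.grid(x = xs, y = xs)
  z <- with_seed(spec$seed, {
    spec$head_plane_z +
      if (spec$jitter_sigma > 0)
        stats::rnorm(nrow(g), sd = spec$jitter_sigma) else rep(0, nrow(g))
  })
  atoms <- data.frame(
    elem = c(rep("P", nrow(g)), "O"),
    atom = c(rep("P", nrow(g)), "O1"),
    resid = c(rep("POP", nrow(g)), "Q1C"),
    resno = c(seq_len(nrow(g)), nrow(g) + 1L),
    chain = c(rep("L", nrow(g)), "Q"),
    x = c(g$x, 0), y = c(g$y, 0),
    z = c(z, spec$head_plane_z + spec$ligand_height),
    occ = 1,
    stringsAsFactors = FALSE)
  structure_model(atoms)
}
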