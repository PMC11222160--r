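plane_cloud <- function(n = 500, tilt_deg = 0, jitter = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n, -100, 100); y <- runif(n, -100, 100)
  z <- rnorm(n, sd = jitter)
  pts <- cbind(x, y, z)
  if (tilt_deg != 0) {
    a <- tilt_deg * pi / 180
    R <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
                byrow = TRUE)
    pts <- pts %*% t(R)
  }
  cryomem:::as_point_cloud(pts)
}

test_that("membrane point sampling respects threshold, mask and count floor", {
  spec <- sim_spec_3d(grid_size = 48, voxel_size = 4, surface_kind = "plane")
  sim <- simulate_membrane_volume(spec)
  cl <- sample_membrane_points(sim$volume, 0.5)
  # points concentrate in the two shells
  expect_true(all(abs(abs(cl$points[, 3]) - 20) < 12))
  expect_error(sample_membrane_points(sim$volume, 5), "range")
  # thresholds sweep: point count non-increasing in threshold
  counts <- vapply(c(0.2, 0.5, 0.8), function(t)
    nrow(sample_membrane_points(sim$volume, t)$points), 0)
  expect_true(all(diff(counts) <= 0))
  # exclusion mask removes points
  mask <- array(FALSE, dim(sim$volume$data))
  mask[1:24, , ] <- TRUE
  cl2 <- sample_membrane_points(sim$volume, 0.5, mask)
  expect_lt(nrow(cl2$points), nrow(cl$points))
  expect_true(all(cl2$points[, 1] > 0))
})

test_that("reference plane fit is exact on coplanar points and accurate when tilted", {
  cl <- plane_cloud()
  fit <- fit_reference_plane(cl)
  expect_lt(fit$rms, 1e-9)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)

  cl25 <- plane_cloud(tilt_deg = 25, jitter = 0.5, seed = 3)
  f25 <- fit_reference_plane(cl25)
  true_n <- c(0, -sin(25 * pi / 180), cos(25 * pi / 180))
  ang <- acos(min(1, abs(sum(f25$normal * true_n)))) * 180 / pi
  expect_lt(ang, 0.1)
  # the rotation maps the normal to +z
  expect_equal(as.vector(f25$rotation %*% f25$normal), c(0, 0, 1),
               tolerance = 1e-9)

  # sign symmetry: flipping the cloud flips the plane with it
  flipped <- cryomem:::as_point_cloud(cl25$points %*% diag(c(1, -1, -1)))
  ff <- fit_reference_plane(flipped)
  flipped_n <- c(0, sin(25 * pi / 180), -cos(25 * pi / 180))
  expect_equal(abs(sum(ff$normal * flipped_n)), 1, tolerance = 1e-6)

  # markers pin the sign of the normal
  mk <- matrix(c(0, 0, 50), 1, 3) %*% diag(c(1, 1, 1))
  fm <- fit_reference_plane(cl, markers = mk)
  expect_gt(fm$normal[3], 0)
  fm2 <- fit_reference_plane(cl, markers = -mk)
  expect_lt(fm2$normal[3], 0)

  expect_error(fit_reference_plane(cryomem:::as_point_cloud(
    cbind(1:50, 1:50, 1:50))), "collinear")
})

test_that("leaflet surfaces recover thickness and the analytic sphere", {
  spec <- sim_spec_3d(grid_size = 64, voxel_size = 4, surface_kind = "plane")
  sim <- simulate_membrane_volume(spec)
  cl <- sample_membrane_points(sim$volume, 0.5)
  fit <- fit_leaflet_surfaces(cl)
  th <- fit$z_upper - fit$z_lower
  expect_true(all(abs(th[!is.na(th)] - 40) <= 2))
  expect_true(all(fit$z_upper >= fit$z_mid, na.rm = TRUE))
  expect_true(all(fit$z_lower <= fit$z_mid, na.rm = TRUE))

  specs <- sim_spec_3d(grid_size = 64, voxel_size = 4,
                       surface_kind = "sphere_cap",
                       surface_params = list(R = 500))
  sims <- simulate_membrane_volume(specs)
  cls <- sample_membrane_points(sims$volume, 0.5)
  fits <- fit_leaflet_surfaces(cls)
  g <- expand.grid(x = fits$x, y = fits$y)
  za <- matrix(sims$f(g$x, g$y), length(fits$x))
  dev <- fits$z_mid - za
  expect_lt(sqrt(mean(dev^2, na.rm = TRUE)), 2)
})

test_that("a jittered plane cloud fits back to the plane within 1 Å", {
  set.seed(11)
  n <- 4000
  pts <- cbind(runif(n, -120, 120), runif(n, -120, 120), rnorm(n, sd = 3))
  cl <- cryomem:::as_point_cloud(pts)
  fit <- suppressWarnings(fit_leaflet_surfaces(cl))
  interior <- fit$z_mid[4:(length(fit$x) - 3), 4:(length(fit$y) - 3)]
  expect_lt(max(abs(interior), na.rm = TRUE), 1)
})

test_that("monolayer-like input warns", {
  set.seed(2)
  pts <- cbind(runif(400, -80, 80), runif(400, -80, 80), rnorm(400, 20, 0.1))
  expect_warning(fit_leaflet_surfaces(cryomem:::as_point_cloud(pts)),
                 "monolayer")
})

test_that("gaussian surface smoothing is an identity at sigma 0 and attenuates ripples", {
  spec <- sim_spec_3d(grid_size = 64, voxel_size = 4, surface_kind = "plane")
  sim <- simulate_membrane_volume(spec)
  cl <- sample_membrane_points(sim$volume, 0.5)
  fit <- fit_leaflet_surfaces(cl)
  expect_identical(smooth_surface(fit, 0), fit)

  # plane input -> plane output for any sigma
  sm <- smooth_surface(fit, 25)
  expect_lt(max(abs(sm$z_mid - mean(fit$z_mid, na.rm = TRUE)), na.rm = TRUE),
            0.5)

  # high-frequency sinusoid attenuated per the Gaussian transfer function
  xa <- seq(0, 300, by = 5); ya <- xa
  lam <- 30; A <- 5
  z <- outer(sin(2 * pi * xa / lam), rep(1, length(ya)))
  model <- structure(list(x = xa, y = ya, z_mid = A * z, z_upper = A * z + 20,
                          z_lower = A * z - 20, rotation = diag(3),
                          thickness = 40, grid_spacing = 5),
                     class = "bilayer_surface")
  sigma <- 15
  out <- smooth_surface(model, sigma)
  atten_expected <- exp(-2 * pi^2 * sigma^2 / lam^2)
  interior <- out$z_mid[20:41, 20:41]
  atten <- max(abs(interior)) / A
  expect_lt(atten, 0.1)
  expect_lt(abs(atten - atten_expected), 0.05)
})

test_that("curvature is exact for plane, sphere and sinusoid height fields", {
  # plane
  xa <- seq(-120, 120, by = 10)
  mkmodel <- function(z) structure(
    list(x = xa, y = xa, z_mid = z, z_upper = z + 20, z_lower = z - 20,
         rotation = diag(3), thickness = 40, grid_spacing = 10),
    class = "bilayer_surface")
  zp <- matrix(3.5, length(xa), length(xa))
  cfp <- surface_curvature(mkmodel(zp))
  expect_lt(max(abs(cfp$H), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(cfp$K), na.rm = TRUE), 1e-9)

  # sphere cap (dome, convex towards +z): H = +1/R, K = 1/R^2
  R <- 500
  g <- expand.grid(x = xa, y = xa)
  zs <- matrix(sqrt(R^2 - g$x^2 - g$y^2) - R, length(xa))
  cfs <- surface_curvature(mkmodel(zs))
  s <- curvature_summary(cfs)
  expect_equal(s$H_median, 10 / R, tolerance = 0.01)
  expect_equal(s$K_median, 100 / R^2, tolerance = 0.01)

  # sinusoid: H at the crest = A (2 pi / lambda)^2 / 2 (convex up)
  A <- 15; lam <- 250
  zn <- matrix(A * sin(2 * pi * g$x / lam), length(xa))
  cfn <- surface_curvature(mkmodel(zn))
  crest <- which.min(abs(xa - lam / 4))
  H_true <- A * (2 * pi / lam)^2 / 2 * 10   # nm^-1, convex towards +z
  expect_equal(stats::median(cfn$H[crest, ], na.rm = TRUE), H_true,
               tolerance = 0.05)
})

test_that("full 3D stage recovers sphere curvature across radii", {
  suite <- sphere_recovery_suite(radii = c(300, 500, 1000))
  expect_true(all(abs(suite$H_rel_err) <= 0.05))
  expect_true(all(abs(suite$K_rel_err) <= 0.10))
})

test_that("recovered curvature is invariant to a rigid rotation of the cloud", {
  spec <- sim_spec_3d(grid_size = 64, voxel_size = 4,
                      surface_kind = "sphere_cap",
                      surface_params = list(R = 500))
  sim <- simulate_membrane_volume(spec)
  cl <- sample_membrane_points(sim$volume, 0.5)
  base <- curvature_summary(surface_curvature(smooth_surface(
    fit_leaflet_surfaces(cl), 10)))

  a <- 18 * pi / 180
  R3 <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
               byrow = TRUE)
  rot_pts <- cl$points %*% t(R3)
  cl_rot <- cryomem:::as_point_cloud(rot_pts, density = cl$density)
  # a matrix-side marker (above the dome) pins the normal's sign
  marker <- matrix(c(0, 0, 200), 1, 3) %*% t(R3)
  pl <- fit_reference_plane(cl_rot, markers = marker)
  realigned <- cryomem:::as_point_cloud(
    sweep(cl_rot$points, 2, pl$centroid) %*% t(pl$rotation),
    density = cl$density)
  rec <- curvature_summary(surface_curvature(smooth_surface(
    fit_leaflet_surfaces(realigned), 10)))
  expect_lt(abs(rec$H_median / base$H_median - 1), 0.01)
})

test_that("convex and concave regions have opposite curvature signs", {
  # two-lobe fixture: a sinusoid has a convex crest (the CI-heel-like
  # region) and a concave trough (the CIII2-like region)
  spec <- sim_spec_3d(grid_size = 64, voxel_size = 4,
                      surface_kind = "sinusoid",
                      surface_params = list(amplitude = 15, wavelength = 250))
  sim <- simulate_membrane_volume(spec)
  cl <- sample_membrane_points(sim$volume, 0.5)
  fit <- fit_leaflet_surfaces(cl, bandwidth = 20, grid_spacing = 8)
  cf <- surface_curvature(smooth_surface(fit, 8))
  crest <- which.min(abs(fit$x - 250 / 4))
  trough <- which.min(abs(fit$x + 250 / 4))
  H_crest <- stats::median(cf$H[crest, ], na.rm = TRUE)
  H_trough <- stats::median(cf$H[trough, ], na.rm = TRUE)
  expect_gt(H_crest, 0)
  expect_lt(H_trough, 0)
})

test_that("planar lattice deformation lands heads on the leaflet surfaces", {
  lattice <- make_planar_bilayer_lattice(extent = 90, spacing = 8,
                                         thickness = 40)
  expect_setequal(unique(lattice$elem), c("P", "C"))

  # plane surface: deformation is a pure z-translation
  xa <- seq(-120, 120, by = 10)
  zp <- matrix(7, length(xa), length(xa))
  plane <- structure(list(x = xa, y = xa, z_mid = zp, z_upper = zp + 20,
                          z_lower = zp - 20, rotation = diag(3),
                          thickness = 40, grid_spacing = 10),
                     class = "bilayer_surface")
  dp <- deform_planar_bilayer(lattice, plane)
  expect_equal(dp$x, lattice$x[seq_len(nrow(dp))], tolerance = 1e-9)
  expect_equal(dp$z, lattice$z[seq_len(nrow(dp))] + 7, tolerance = 1e-9)

  # sphere cap: head atoms land within 2 Å of the offset spheres R -/+ 20
  R <- 500
  g <- expand.grid(x = xa, y = xa)
  zs <- matrix(sqrt(R^2 - g$x^2 - g$y^2) - R, length(xa))
  sph <- structure(list(x = xa, y = xa, z_mid = zs, z_upper = zs, z_lower = zs,
                        rotation = diag(3), thickness = 40,
                        grid_spacing = 10),
                   class = "bilayer_surface")
  ds <- suppressMessages(deform_planar_bilayer(lattice, sph))
  heads <- ds[ds$elem == "P", ]
  # distance from the sphere centre (0, 0, -R)
  r_head <- sqrt(heads$x^2 + heads$y^2 + (heads$z + R)^2)
  delta <- ifelse(heads$chain == "U", 20, -20)
  expect_lt(max(abs(r_head - (R + delta))), 2)

  # first-order isometry: nearest-neighbour spacing preserved within 5%
  # (checked on the near-mid-plane tail atoms; head planes carry the real
  # delta*kappa leaflet stretch of a curved bilayer)
  up <- ds[ds$atom == "C2", ]
  up0 <- lattice[lattice$atom == "C2", ]
  up0 <- up0[seq_len(nrow(up)), ]
  nn_dist <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")])
    d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
    diag(d2) <- Inf
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  expect_lt(max(abs(nn_dist(up) / nn_dist(up0) - 1)), 0.05)

  expect_error(deform_planar_bilayer(
    make_planar_bilayer_lattice(extent = 50, thickness = 100), plane),
    "exceeds")
})
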