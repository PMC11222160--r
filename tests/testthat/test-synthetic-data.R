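test_that("empty scene gives an all-zero image and generation is deterministic", {
  spec <- sim_spec_2d(image_size = 64, pixel_size = 4, segments = list(),
                      n_blobs = 0, noise_model = "none", seed = 3)
  sim <- simulate_micrograph(spec)
  expect_true(all(sim$image$data == 0))

  spec2 <- sim_spec_2d(image_size = 96, pixel_size = 4,
                       segments = list(ground_truth_segment(kappa = 0.01,
                                                            length = 250)),
                       n_blobs = 2, snr = 0.8, seed = 11)
  a <- simulate_micrograph(spec2)
  b <- simulate_micrograph(spec2)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$blobs, b$blobs)
  # ground truth returned verbatim
  expect_identical(a$segments, spec2$segments)
  # different seed changes the noise
  c <- simulate_micrograph(sim_spec_2d(image_size = 96, pixel_size = 4,
                                       segments = spec2$segments,
                                       n_blobs = 2, snr = 0.8, seed = 12))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("rendered straight segment matches the bilayer profile generator", {
  sim <- make_average(kappa = 0, theta = 0, snr = Inf)
  img <- sim$image
  tmpl <- simulate_bilayer_projection(0, 400, 160, 4)
  expect_equal(img$data, tmpl$data, tolerance = 1e-12)
})

test_that("measured SNR matches the requested value within 10%", {
  seg <- ground_truth_segment(kappa = 0.005, length = 600)
  for (snr in c(0.5, 2)) {
    spec <- sim_spec_2d(image_size = 256, pixel_size = 4,
                        segments = list(seg), snr = snr, seed = 21)
    noisy <- simulate_micrograph(spec)$image
    clean <- simulate_micrograph(
      sim_spec_2d(image_size = 256, pixel_size = 4, segments = list(seg),
                  noise_model = "none"))$image
    measured <- var(as.vector(clean$data)) /
      var(as.vector(noisy$data - clean$data))
    expect_lt(abs(measured / snr - 1), 0.10)
  }
})

test_that("em_dark contrast inverts the sign", {
  seg <- ground_truth_segment(length = 300)
  pos <- simulate_micrograph(sim_spec_2d(segments = list(seg),
                                         noise_model = "none"))
  neg <- simulate_micrograph(sim_spec_2d(segments = list(seg),
                                         noise_model = "none",
                                         contrast = "em_dark"))
  expect_identical(neg$image$data, -pos$image$data)
})

test_that("segments crossing the border warn and are truncated", {
  seg <- ground_truth_segment(centre = c(280, 0), length = 400)
  spec <- sim_spec_2d(image_size = 160, pixel_size = 4,
                      segments = list(seg), noise_model = "none")
  expect_warning(sim <- simulate_micrograph(spec), "truncated")
  expect_true(all(is.finite(sim$image$data)))
})

test_that("blobs avoid the membrane exclusion zone", {
  seg <- ground_truth_segment(kappa = 0.01, length = 500)
  spec <- sim_spec_2d(image_size = 256, pixel_size = 4,
                      segments = list(seg), n_blobs = 6, snr = 1, seed = 5)
  sim <- simulate_micrograph(spec)
  expect_identical(nrow(sim$blobs), 6L)
  for (i in seq_len(6)) {
    cs <- arc_coords(sim$blobs$x[i], sim$blobs$y[i], seg)
    near <- abs(cs$n) < seg$thickness & abs(cs$s) < seg$length / 2
    expect_false(near)
  }
})

test_that("plane volume concentrates density at z = +/- thickness/2", {
  spec <- sim_spec_3d(grid_size = 48, voxel_size = 4, surface_kind = "plane",
                      thickness = 40)
  sim <- simulate_membrane_volume(spec)
  zprofile <- apply(sim$volume$data, 3, mean)
  ax <- (seq_len(48) - (48 + 1) / 2) * 4
  peak_up <- ax[ax > 0][which.max(zprofile[ax > 0])]
  peak_dn <- ax[ax < 0][which.max(zprofile[ax < 0])]
  expect_lt(abs(peak_up - 20), 4)   # within one voxel
  expect_lt(abs(peak_dn + 20), 4)
  expect_equal(sim$f(10, -30), 0)
})

test_that("sphere-cap volume's bright voxels satisfy the sphere equation", {
  R <- 500
  spec <- sim_spec_3d(grid_size = 64, voxel_size = 4,
                      surface_kind = "sphere_cap",
                      surface_params = list(R = R, z0 = 0))
  sim <- simulate_membrane_volume(spec)
  # mid-surface points satisfy x^2 + y^2 + (z - z_centre)^2 = R^2, with the
  # sphere centre one radius below the apex (z0 = 0)
  xs <- seq(-100, 100, by = 25)
  z <- sim$f(xs, rep(15, length(xs)))
  lhs <- xs^2 + 15^2 + (z - (0 - R))^2
  expect_equal(lhs, rep(R^2, length(xs)), tolerance = 1e-10)
})

test_that("embedded protein cylinder crosses both shells", {
  spec <- sim_spec_3d(grid_size = 48, voxel_size = 4, surface_kind = "plane",
                      include_protein = TRUE)
  sim <- simulate_membrane_volume(spec)
  base <- simulate_membrane_volume(
    sim_spec_3d(grid_size = 48, voxel_size = 4, surface_kind = "plane"))
  added <- sim$volume$data - base$volume$data
  expect_gt(sum(added > 1), 0)
  # the cylinder spans from below the lower shell to above the upper shell
  zidx <- which(apply(added, 3, max) > 1)
  ax <- (seq_len(48) - (48 + 1) / 2) * 4
  expect_lt(min(ax[zidx]), -20)
  expect_gt(max(ax[zidx]), 20)
})

test_that("surface exiting the grid is rejected with a clear error", {
  expect_error(sim_spec_3d(grid_size = 48, voxel_size = 4,
                           surface_kind = "sphere_cap",
                           surface_params = list(R = 40)), "R")
  spec <- sim_spec_3d(grid_size = 48, voxel_size = 4,
                      surface_kind = "sinusoid",
                      surface_params = list(amplitude = 500, wavelength = 100))
  expect_error(simulate_membrane_volume(spec), "exits the grid")
})

test_that("fixture model encodes exact headgroup and ligand heights", {
  m0 <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                              ligand_height = 0))
  p <- select_atoms(m0, elem = "P")
  lig <- select_atoms(m0, resid = "Q1C")
  expect_equal(mean(p$z), 0)
  expect_equal(lig$z, 0)

  m20 <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                               ligand_height = 20))
  expect_equal(select_atoms(m20, resid = "Q1C")$z - mean(select_atoms(m20, elem = "P")$z),
               20)

  # jittered lattice: mean z within ~SEM of the head plane (n >= 400)
  mj <- make_fixture_model(model_fixture_spec(lattice_extent = 80,
                                              lattice_spacing = 8,
                                              jitter_sigma = 2, seed = 9))
  pj <- select_atoms(mj, elem = "P")
  expect_gte(nrow(pj), 400)
  expect_lt(abs(mean(pj$z)), 3 * 2 / sqrt(nrow(pj)))
  # determinism
  mj2 <- make_fixture_model(model_fixture_spec(lattice_extent = 80,
                                               lattice_spacing = 8,
                                               jitter_sigma = 2, seed = 9))
  expect_identical(mj$z, mj2$z)
})

test_that("ground truth round-trips losslessly through the STAR writer", {
  segs <- list(ground_truth_segment(centre = c(12.25, -31.5), theta = 17.5,
                                    kappa = 0.0125, length = 310,
                                    thickness = 42),
               ground_truth_segment(centre = c(-80, 4), theta = 175,
                                    kappa = -0.02, length = 250))
  path <- withr::local_tempfile(fileext = ".star")
  write_segments_star(segs, path)
  back <- read_segments_star(path)
  expect_equal(back, segs)
})
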