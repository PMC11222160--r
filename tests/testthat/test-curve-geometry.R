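test_that("radon orientation recovers theta and the normal offset", {
  # canonical straight membrane
  a0 <- make_average(kappa = 0, theta = 0, snr = Inf)
  r0 <- radon_orientation(a0$image)
  expect_lt(min(r0$theta, 180 - r0$theta), 1)

  # rotated 17 degrees and offset 12 Å along the normal
  n17 <- c(-sin(17 * pi / 180), cos(17 * pi / 180))
  a17 <- make_average(kappa = 0, theta = 17, centre = 12 * n17, snr = Inf)
  r17 <- radon_orientation(a17$image)
  expect_lt(abs(r17$theta - 17), 0.5)
  expect_lt(abs(r17$offset_normal - 12), 4)        # one pixel
  expect_lt(sqrt(sum((r17$centre_offset - 12 * n17)^2)), 4)

  # theta is defined mod 180: a 180-degree rotated copy gives the same theta
  rot <- rotate_image(a17$image, 180)
  r_rot <- radon_orientation(rot)
  d <- abs(r_rot$theta - r17$theta)
  expect_lt(min(d, 180 - d), 0.5)

  expect_error(radon_orientation(mem_image(matrix(1, 64, 64), 4)),
               "no linear feature")
})

test_that("curvature estimation hits the bank grid and interpolates between", {
  bank <- test_bank()
  a <- make_average(kappa = 0.010, theta = 0, snr = Inf)
  ec <- estimate_curvature(a$image, bank, radon_orientation(a$image)$theta)
  expect_lt(abs(ec$kappa - 0.010), 5e-4)
  expect_false(ec$low_confidence)

  a0 <- make_average(kappa = 0, theta = 0, snr = Inf)
  ec0 <- estimate_curvature(a0$image, bank, radon_orientation(a0$image)$theta)
  expect_lt(abs(ec0$kappa), 5e-4)

  # off-grid curvature is recovered by parabolic interpolation
  ah <- make_average(kappa = 0.0125, theta = 0, snr = Inf)
  ech <- estimate_curvature(ah$image, bank, radon_orientation(ah$image)$theta)
  expect_lt(abs(ech$kappa - 0.0125), 5e-4)
})

test_that("curvature estimation is invariant to affine intensity rescaling", {
  bank <- test_bank()
  a <- make_average(kappa = 0.015, theta = 40, snr = 2, seed = 31)
  th <- radon_orientation(a$image)$theta
  e1 <- estimate_curvature(a$image, bank, th)
  scaled <- mem_image(-2.5 * a$image$data + 7, 4)
  # NCC magnitude is scale-free; a sign flip inverts contrast, so compare
  # against the positive rescaling
  scaled_pos <- mem_image(2.5 * a$image$data + 7, 4)
  e2 <- estimate_curvature(scaled_pos, bank, th)
  expect_equal(e2$kappa, e1$kappa, tolerance = 1e-9)
  expect_equal(e2$score, e1$score, tolerance = 1e-9)
})

test_that("low-confidence curvature estimates warn", {
  bank <- test_bank()
  set.seed(2)
  noise <- mem_image(matrix(rnorm(160^2), 160, 160), 4)
  # noise has no membrane: score is weak
  expect_warning(ec <- estimate_curvature(noise, bank, 0), "low-confidence")
  expect_true(ec$low_confidence)
})

test_that("transform_curve composes rigidly and preserves the arc", {
  cv <- arc_segment(centre = c(30, -12), theta = 25, kappa = 0.013,
                    length = 350, thickness = 42)
  id <- alignment_params()
  expect_equal(transform_curve(cv, id), cv)

  rot90 <- transform_curve(cv, alignment_params(rotation = 90))
  expect_equal(rot90$theta, (25 + 90) %% 180)
  expect_equal(rot90$centre, c(12, 30))
  expect_equal(rot90$kappa, cv$kappa)
  expect_equal(rot90$length, cv$length)

  # mirror flips the curvature sign (compared in the canonical
  # representation, since the stored theta is folded mod 180)
  mir <- transform_curve(cv, alignment_params(mirror = TRUE))
  expect_equal(abs(mir$kappa), abs(cv$kappa))
  can_m <- canonical_arc(mir$theta, mir$kappa)
  can_0 <- canonical_arc(cv$theta, cv$kappa)
  expect_equal(can_m$theta, -can_0$theta)
  expect_equal(can_m$kappa, -can_0$kappa)

  # transform then inverse-transform returns the original
  for (seed in 1:5) {
    set.seed(seed)
    al <- alignment_params(rotation = runif(1, -180, 180),
                           shift = runif(2, -50, 50),
                           mirror = runif(1) > 0.5)
    back <- transform_curve(transform_curve(cv, al), invert_alignment(al))
    expect_equal(back$centre, cv$centre, tolerance = 1e-9)
    expect_equal(back$theta, cv$theta, tolerance = 1e-9)
    expect_equal(back$kappa, cv$kappa, tolerance = 1e-9)
  }
})

test_that("a folded theta representation preserves the arc geometry", {
  # (theta, kappa) folded by 180 degrees must render identically
  a <- arc_segment(centre = c(5, 8), theta = 200, kappa = 0.015, length = 300)
  b <- arc_segment(centre = c(5, 8), theta = 20, kappa = -0.015, length = 300)
  expect_equal(a$theta, b$theta)
  expect_equal(a$kappa, b$kappa)
  spec <- bilayer_profile_spec()
  ia <- cryomem:::render_arc(a, c(96, 96), 4, spec)
  ib <- cryomem:::render_arc(b, c(96, 96), 4, spec)
  expect_identical(ia$data, ib$data)
})

test_that("centre refinement recovers constructed sub-pixel shifts", {
  a <- make_average(kappa = 0.01, theta = 10, snr = Inf)
  shifted <- translate_image(a$image, 3.4 * 4, 0)
  rc <- refine_center(shifted, a$image, search_radius = 40)
  expect_lt(abs(rc$dx / 4 - 3.4), 0.2)
  expect_lt(abs(rc$dy / 4), 0.2)
  expect_true(rc$converged)

  self <- refine_center(a$image, a$image, search_radius = 40)
  expect_lt(abs(self$dx), 1e-6)
  expect_lt(abs(self$dy), 1e-6)
  expect_gte(self$ncc, 0.999)

  set.seed(77)
  noise <- mem_image(matrix(rnorm(160^2), 160, 160), 4)
  expect_warning(refine_center(noise, a$image, search_radius = 40),
                 "unconverged")
  expect_error(refine_center(a$image, a$image, search_radius = 1000),
               "search_radius")
})

test_that("end-to-end 2D recovery meets the (0.5 deg, 2 px, 0.002 nm^-1) contract", {
  df <- curvature_recovery_suite(kappas = c(0, 0.005, 0.010, 0.015, 0.020),
                                 n_rep = 2, snr = Inf, seed = 42)
  expect_identical(nrow(df), 10L)
  expect_lt(max(df$theta_err), 0.5)
  expect_lt(max(df$centre_err_px), 2)
  expect_lt(max(df$kappa_err), 0.002)
})

test_that("noisy curvature recovery is unbiased at snr 0.5", {
  df <- curvature_recovery_suite(kappas = 0.015, n_rep = 8, snr = 0.5,
                                 seed = 7)
  expect_lte(mean(df$kappa_err), 0.002)
})
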