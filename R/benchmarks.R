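#' Curvature / orientation / centre recovery on synthetic class averages
#'
#' Generates seeded synthetic class averages of single membrane arcs with
#' known (theta, centre, kappa), runs the full per-average estimation
#' pipeline ([fit_membrane_curve()]) and tabulates recovery errors. This is
#' the standard evaluation of the 2D estimators.
#'
#' @param kappas true curvatures, nm^-1 (recycled over replicates).
#' @param n_rep replicates per kappa (different seeds, random theta and
#'   centre offsets).
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param seed base seed.
#' @param bank a [template_bank()]; built with defaults when NULL.
#' @param image_size,pixel_size raster of the synthetic averages.
#' @param length membrane arc length, Å.
#' @return data.frame with one row per average: true and estimated
#'   parameters, `theta_err` (degrees), `centre_err_px`, `kappa_err`
#'   (nm^-1).
#' @export
curvature_recovery_suite <- function(kappas = c(0, 0.005, 0.010, 0.015, 0.020),
                                     n_rep = 1, snr = Inf, seed = 1,
                                     bank = NULL, image_size = 160,
                                     pixel_size = 4, length = 400) {
  if (is.null(bank))
    bank <- make_template_bank(n_templates = 21, length = length,
                               image_size = 128, pixel_size = pixel_size)
  cases <- expand.grid(rep = seq_len(n_rep), kappa = kappas)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    k <- cases$kappa[i]
    case_seed <- seed + 1000 * i
    pars <- with_seed(case_seed, list(
      theta = stats::runif(1, 0, 180),
      off = stats::runif(2, -2, 2) * pixel_size))
    seg <- ground_truth_segment(centre = pars$off, theta = pars$theta,
                                kappa = k, length = length)
    spec <- sim_spec_2d(image_size = image_size, pixel_size = pixel_size,
                        segments = list(seg),
                        noise_model = if (is.finite(snr)) "gaussian" else "none",
                        snr = if (is.finite(snr)) snr else 1,
                        seed = case_seed)
    avg <- simulate_micrograph(spec)$image
    fit <- suppressWarnings(fit_membrane_curve(avg, bank))
    truth <- canonical_arc(pars$theta, k)
    th_err <- abs(fit$theta - truth$theta)
    th_err <- min(th_err, 180 - th_err)
    # both angles are canonical in (-90, 90]; when the estimate falls on the
    # other side of the +/-90 wrap, its curvature sign flips representation
    k_est <- if (abs(fit$theta - truth$theta) > 90) -fit$kappa else fit$kappa
    rows <- data.frame(
      kappa_true = k, theta_true = truth$theta,
      centre_x_true = pars$off[1], centre_y_true = pars$off[2],
      kappa_est = k_est, theta_est = fit$theta,
      centre_x_est = fit$curve$centre[1], centre_y_est = fit$curve$centre[2],
      score = fit$score,
      theta_err = th_err,
      centre_err_px = sqrt(sum((fit$curve$centre - pars$off)^2)) / pixel_size,
      kappa_err = abs(k_est - truth$kappa))
    rows
  })
  do.call(rbind, rows)
}

#' Membrane detection recall on the standard synthetic suite
#'
#' Seeded micrographs, each with three disjoint membrane segments at snr
#' 0.5, are scanned with the matched filter; picks within `match_tol_px`
#' of a true centre count as hits.
#'
#' @param n_images number of seeded micrographs.
#' @param seed base seed.
#' @param bank detection bank (a coarse 5-template bank when NULL).
#' @param threshold picking threshold.
#' @param angle_step rotation sampling of the matched filter, degrees.
#' @param snr signal-to-noise ratio of the suite.
#' @param match_tol_px hit tolerance in pixels.
#' @return list with `recall`, `false_positives_per_image`, and the per
#'   image data.frame `detail`.
#' @export
detection_recall_suite <- function(n_images = 10, seed = 100, bank = NULL,
                                   threshold = 0.4, angle_step = 5,
                                   snr = 0.5, match_tol_px = 4) {
  pixel_size <- 4
  if (is.null(bank))
    bank <- make_template_bank(n_templates = 5, length = 300,
                               image_size = 96, pixel_size = pixel_size)
  per_image <- lapply(seq_len(n_images), function(i) {
    img_seed <- seed + i
    segs <- with_seed(img_seed * 7, {
      lapply(1:3, function(j) {
        ground_truth_segment(
          centre = c(stats::runif(1, -250, 250),
                     (j - 2) * 320 + stats::runif(1, -60, 60)),
          theta = stats::runif(1, 0, 180),
          kappa = sample(bank$kappas, 1),
          length = 300)
      })
    })
    spec <- sim_spec_2d(image_size = 256, pixel_size = pixel_size,
                        segments = segs, snr = snr, seed = img_seed)
    sim <- suppressWarnings(simulate_micrograph(spec))
    field <- match_templates(sim$image, bank, angle_step = angle_step)
    picks <- pick_segments(field, threshold = threshold, nms_radius = 150)
    truth <- do.call(rbind, lapply(segs, function(s)
      data.frame(x = s$centre[1], y = s$centre[2])))
    hit <- rep(FALSE, nrow(truth))
    fp <- 0
    for (p in seq_len(nrow(picks))) {
      d <- sqrt((picks$centre_x_A[p] - truth$x)^2 +
                (picks$centre_y_A[p] - truth$y)^2) / pixel_size
      j <- which.min(d)
      if (d[j] <= match_tol_px && !hit[j]) hit[j] <- TRUE else fp <- fp + 1
    }
    data.frame(image = i, n_true = nrow(truth), n_hit = sum(hit),
               n_false = fp)
  })
  detail <- do.call(rbind, per_image)
  list(recall = sum(detail$n_hit) / sum(detail$n_true),
       false_positives_per_image = mean(detail$n_false),
       detail = detail)
}

#' Alignment benefit of membrane weakening
#'
#' Thirty (by default) seeded synthetic particles share one globular
#' "protein" blob at varying positions alongside a membrane whose signal
#' dominates the raw images. The blob is registered by normalized
#' cross-correlation against a blob template, before and after membrane
#' weakening; registration succeeds when the correlation peak falls within
#' `success_tol_A` of the true blob position.
#'
#' @param n_images number of particles.
#' @param seed base seed.
#' @param lambda weakening weight used for the "after" arm.
#' @param snr particle signal-to-noise ratio.
#' @param blob_amp blob peak amplitude relative to the membrane head bands.
#' @param success_tol_A registration success tolerance, Å.
#' @return list with `success_before`, `success_after` (fractions) and the
#'   per-image data.frame `detail`.
#' @export
alignment_benefit_suite <- function(n_images = 30, seed = 500, lambda = 1,
                                    snr = 2, blob_amp = 0.5,
                                    success_tol_A = 20) {
  pixel_size <- 4
  image_size <- 128
  blob_sigma <- 15
  profile <- bilayer_profile_spec()
  curve <- arc_segment(centre = c(0, -60), theta = 0, kappa = 0.01,
                       length = 480)
  cfg <- weaken_config(lambda = lambda)
  # blob template for registration
  tg <- pixel_grid(c(48, 48), pixel_size)
  tmpl <- blob_amp * exp(-(tg$x^2 + tg$y^2) / (2 * blob_sigma^2))
  register <- function(img) {
    prep <- ncc_prep(img$data, 24)
    ncc <- ncc_apply(prep, tmpl)
    i <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
    c(dr = signed_shift(i[1], nrow(ncc)), dc = signed_shift(i[2], ncol(ncc)))
  }
  per_image <- lapply(seq_len(n_images), function(i) {
    img_seed <- seed + i
    # blob placed along the membrane at a varying arc position, offset to
    # the matrix side just outside the soft mask
    s_pos <- with_seed(img_seed * 3, stats::runif(1, -160, 160))
    p <- arc_point(curve, s_pos, 60)
    g <- pixel_grid(c(image_size, image_size), pixel_size)
    seg_img <- render_arc(curve, c(image_size, image_size), pixel_size,
                          profile)
    blob <- blob_amp * exp(-((g$x - p$x)^2 + (g$y - p$y)^2) /
                             (2 * blob_sigma^2))
    signal <- seg_img$data + blob
    noise_sd <- sqrt(stats::var(as.vector(signal)) / snr)
    noisy <- with_seed(img_seed,
      signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                      image_size, image_size))
    img <- mem_image(noisy, pixel_size)
    est <- estimate_membrane_signal(img, curve, cfg)
    weak <- weaken_membrane(img, est, lambda)
    # the correlation field is indexed by shift from the frame centre
    centre_rc <- xy_to_rc(p$x, p$y, dim(img$data), pixel_size)
    true_shift <- c(centre_rc$row - (image_size + 1) / 2,
                    centre_rc$col - (image_size + 1) / 2)
    err_px <- function(sh) sqrt(sum((sh - true_shift)^2))
    before <- register(img); after <- register(weak)
    data.frame(image = i,
               err_before_A = err_px(before) * pixel_size,
               err_after_A = err_px(after) * pixel_size)
  })
  detail <- do.call(rbind, per_image)
  list(success_before = mean(detail$err_before_A <= success_tol_A),
       success_after = mean(detail$err_after_A <= success_tol_A),
       detail = detail)
}

#' Sphere-cap curvature recovery across radii
#'
#' Runs the full 3D stage (simulate volume, sample points, fit leaflets,
#' smooth, curvature) on spherical-cap fixtures and compares the interior
#' median mean/Gaussian curvature to the analytic 1/R and 1/R^2.
#'
#' @param radii sphere radii, Å.
#' @param threshold binarization threshold (fraction of the shell maximum).
#' @param bandwidth,grid_spacing,sigma fitting and smoothing parameters, Å.
#' @return data.frame with one row per radius: recovered medians, analytic
#'   values and relative errors.
#' @export
sphere_recovery_suite <- function(radii = c(300, 500, 1000), threshold = 0.5,
                                  bandwidth = 30, grid_spacing = 10,
                                  sigma = 10) {
  rows <- lapply(radii, function(R) {
    spec <- sim_spec_3d(grid_size = 64, voxel_size = 4,
                        surface_kind = "sphere_cap",
                        surface_params = list(R = R, z0 = 0))
    sim <- simulate_membrane_volume(spec)
    cloud <- sample_membrane_points(sim$volume, threshold)
    fit <- fit_leaflet_surfaces(cloud, bandwidth = bandwidth,
                                grid_spacing = grid_spacing)
    cf <- surface_curvature(smooth_surface(fit, sigma))
    s <- curvature_summary(cf)
    data.frame(R_A = R, H_median = s$H_median, K_median = s$K_median,
               H_true = 10 / R, K_true = 100 / R^2,
               H_rel_err = s$H_median * R / 10 - 1,
               K_rel_err = s$K_median * R^2 / 100 - 1)
  })
  do.call(rbind, rows)
}
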