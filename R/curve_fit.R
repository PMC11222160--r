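#' Membrane orientation and centre from a class average (Radon criterion)
#'
#' Estimates the tangent angle of the dominant linear/arc feature of a 2D
#' average as the projection angle maximizing the variance of the 1D
#' projection profile (Radon transform of the image), with a fine local
#' re-scan and parabolic interpolation around the coarse maximum. The centre
#' offset along the membrane normal is the intensity-weighted centroid of
#' the positive part of the profile at the best angle.
#'
#' Angles are tangent angles in degrees modulo 180 (membranes are
#' unoriented lines).
#'
#' @param avg a [mem_image()] class average (density-positive contrast).
#' @param angle_step coarse angular sampling, degrees (default 2).
#' @return list with `theta` (degrees), `centre_offset` (length-2, Å, the
#'   offset of the membrane centre from the image centre along the normal),
#'   `offset_normal` (scalar signed offset, Å) and `sharpness`
#'   (data.frame angle/variance of the coarse scan).
#' @export
radon_orientation <- function(avg, angle_step = 2) {
  stopifnot(inherits(avg, "mem_image"))
  coarse <- seq(0, 180 - angle_step, by = angle_step)
  v_coarse <- vapply(coarse, function(a) projection_variance(avg, a), 0)
  if (diff(range(v_coarse)) <= 1e-12 * max(abs(v_coarse), 1e-300))
    stop("no linear feature: projection variance is constant")
  i <- which.max(v_coarse)
  # fine re-scan around the coarse peak, then parabolic interpolation
  fine_step <- angle_step / 8
  fine <- coarse[i] + seq(-angle_step, angle_step, by = fine_step)
  v_fine <- vapply(fine, function(a) projection_variance(avg, a), 0)
  j <- which.max(v_fine)
  off <- if (j > 1 && j < length(v_fine))
    parabolic_peak(v_fine[j - 1], v_fine[j], v_fine[j + 1])$offset else 0
  theta <- (fine[j] + off * fine_step) %% 180
  prof <- projection_profile(avg, theta)
  w <- pmax(prof$value - stats::median(prof$value), 0)
  d <- if (sum(w) > 0) sum(w * prof$y) / sum(w) else 0
  th <- theta * pi / 180
  list(theta = theta,
       centre_offset = d * c(-sin(th), cos(th)),
       offset_normal = d,
       sharpness = data.frame(angle = coarse, variance = v_coarse))
}

# 1D projection profile perpendicular to a membrane of tangent angle theta:
# rotate the content by -theta (tangent becomes horizontal) and average rows
# inside a circular aperture. The rotation-invariant aperture keeps the
# projection support identical at every angle, so the variance criterion is
# not skewed by the square frame's corners.
projection_profile <- function(avg, theta) {
  g <- pixel_grid(dim(avg$data), avg$pixel_size)
  r_ap <- min(dim(avg$data)) * avg$pixel_size / 2
  ap <- (g$x^2 + g$y^2 <= r_ap^2) * 1
  masked <- mem_image(avg$data * ap, avg$pixel_size)
  rot <- rotate_image(masked, -theta)
  cover <- rotate_image(mem_image(ap, avg$pixel_size), -theta)
  rs <- rowSums(rot$data)
  cs <- rowSums(cover$data)
  ok <- cs > 0.5 * max(cs)
  list(value = rs[ok] / cs[ok], y = g$y[ok, 1], coverage = cs[ok])
}

projection_variance <- function(avg, theta) {
  p <- projection_profile(avg, theta)
  stats::var(p$value)
}

#' Local curvature of a membrane average by template correlation
#'
#' Rotates the average to the canonical (horizontal-tangent) orientation and
#' computes, for every template of the curvature-indexed bank, the maximum
#' locally-normalized cross-correlation over residual translations
#' (frequency-domain search). The curvature estimate is refined beyond the
#' bank's discrete grid by parabolic interpolation of the score over the
#' three templates around the maximum.
#'
#' @param avg a [mem_image()] class average.
#' @param bank a [template_bank()].
#' @param theta tangent angle from [radon_orientation()], degrees.
#' @param search_radius translation search window, Å (default half the
#'   template arc length).
#' @return list with `kappa` (nm^-1), `score` (best NCC), `low_confidence`
#'   (TRUE with a warning when the best score < 0.1) and `scores` (per
#'   template).
#' @export
estimate_curvature <- function(avg, bank, theta, search_radius = NULL) {
  stopifnot(inherits(avg, "mem_image"), inherits(bank, "template_bank"))
  if (is.null(search_radius)) search_radius <- bank$length / 2
  # a tangent angle is defined mod 180, so the canonical rotation is
  # ambiguous by 180 degrees, which flips the bend direction; both branches
  # are scored and the curvature is signed relative to the given theta.
  canon <- rotate_image(avg, -theta)
  flipped <- mem_image(canon$data[rev(seq_len(nrow(canon$data))),
                                  rev(seq_len(ncol(canon$data)))],
                       canon$pixel_size)
  tsz <- nrow(bank$images[[1]]$data)
  win <- window_mask(dim(canon$data), search_radius / avg$pixel_size)
  branch_scores <- function(img) {
    prep <- ncc_prep(img$data, tsz / 2)
    vapply(bank$images, function(tmpl) {
      ncc <- ncc_apply(prep, tmpl$data)
      if (is.null(ncc)) return(-1)
      # sub-pixel peak height (separable parabolic) so the score varies
      # smoothly with kappa instead of being quantized by integer shifts
      nccw <- ifelse(win, ncc, -Inf)
      i <- which(nccw == max(nccw), arr.ind = TRUE)[1, ]
      ny <- nrow(ncc); nx <- ncol(ncc)
      ridx <- function(k, n) ((k - 1) %% n) + 1
      v <- ncc[i[1], i[2]]
      pr <- parabolic_peak(ncc[ridx(i[1] - 1, ny), i[2]], v,
                           ncc[ridx(i[1] + 1, ny), i[2]])
      pc <- parabolic_peak(ncc[i[1], ridx(i[2] - 1, nx)], v,
                           ncc[i[1], ridx(i[2] + 1, nx)])
      v + (pr$value - v) + (pc$value - v)
    }, 0)
  }
  s_pos <- branch_scores(canon)
  s_neg <- branch_scores(flipped)
  ks <- c(-rev(bank$kappas[-1]), bank$kappas)
  ss <- c(rev(s_neg[-1]), s_pos)
  i <- which.max(ss)
  if (i > 1 && i < length(ss)) {
    pk <- parabolic_peak(ss[i - 1], ss[i], ss[i + 1])
    dk <- ks[2] - ks[1]
    kappa <- ks[i] + pk$offset * dk
    score <- pk$value
  } else {
    kappa <- ks[i]
    score <- ss[i]
  }
  low <- score < 0.1
  if (low) warning(sprintf(
    "curvature estimate is low-confidence (best NCC = %.3f < 0.1)", score))
  list(kappa = kappa, score = score, low_confidence = low,
       scores = data.frame(kappa = ks, score = ss))
}

# Logical mask of the central window (circular-shift indexing of
# cross-correlation fields rolled to the centre as in match_templates).
window_mask <- function(shape, radius_px) {
  ny <- shape[1]; nx <- shape[2]
  dr <- signed_shift(seq_len(ny), ny)
  dc <- signed_shift(seq_len(nx), nx)
  outer(dr^2, dc^2, "+") <= radius_px^2
}

#' Refine a membrane centre against a raw image
#'
#' Finds the translation (within a search window) maximizing the normalized
#' cross-correlation between a raw image and the transformed 2D average,
#' with sub-pixel precision by parabolic interpolation. Returns the shift
#' that must be applied to the average to match the raw image.
#'
#' @param raw a [mem_image()] raw particle image.
#' @param transformed_avg a [mem_image()] of the same shape: the class
#'   average already rotated/mirrored into the raw frame.
#' @param search_radius maximum shift searched, Å; must be at most a quarter
#'   of the raw image extent.
#' @return list with `dx`, `dy` (Å), `ncc`, and `converged` (FALSE, with a
#'   warning, when the maximum lies on the search boundary or the
#'   correlation is weak).
#' @export
refine_center <- function(raw, transformed_avg, search_radius = 40) {
  stopifnot(inherits(raw, "mem_image"), inherits(transformed_avg, "mem_image"),
            all(dim(raw$data) == dim(transformed_avg$data)))
  extent <- min(dim(raw$data)) * raw$pixel_size
  if (search_radius > extent / 4)
    stop("search_radius must be <= a quarter of the image extent")
  a <- raw$data - mean(raw$data)
  b <- transformed_avg$data - mean(transformed_avg$data)
  cc <- cross_correlate(a, b) / sqrt(sum(a^2) * sum(b^2))
  ny <- nrow(cc); nx <- ncol(cc)
  r_px <- search_radius / raw$pixel_size
  win <- window_mask(c(ny, nx), r_px)
  cc_win <- ifelse(win, cc, -Inf)
  i <- which(cc_win == max(cc_win), arr.ind = TRUE)[1, ]
  dr <- signed_shift(i[1], ny); dc <- signed_shift(i[2], nx)
  on_boundary <- sqrt(dr^2 + dc^2) >= r_px - 1
  # sub-pixel refinement along rows and columns
  ridx <- function(k, n) ((k - 1) %% n) + 1
  pr <- parabolic_peak(cc[ridx(i[1] - 1, ny), i[2]], cc[i[1], i[2]],
                       cc[ridx(i[1] + 1, ny), i[2]])
  pc <- parabolic_peak(cc[i[1], ridx(i[2] - 1, nx)], cc[i[1], i[2]],
                       cc[i[1], ridx(i[2] + 1, nx)])
  ncc <- max(pr$value, pc$value)
  converged <- !on_boundary && ncc >= 0.2
  if (!converged) warning("unconverged refinement")
  # raster row increases downwards: dy = -row shift
  list(dx = (dc + pc$offset) * raw$pixel_size,
       dy = -(dr + pr$offset) * raw$pixel_size,
       ncc = ncc, converged = converged)
}

#' Fit a full membrane curve to a class average
#'
#' The per-average estimation pipeline: orientation and normal-offset centre
#' from the Radon criterion, curvature from template correlation, then
#' centre refinement by normalized cross-correlation between the average
#' and a rendered model of the fitted arc (which also removes the sagitta
#' bias of the projected-centroid centre for curved membranes).
#'
#' @param avg a [mem_image()] class average.
#' @param bank a [template_bank()].
#' @param angle_step Radon angular sampling, degrees.
#' @param length arc length of the fitted segment, Å (default: the bank's
#'   template length).
#' @return list with `curve` (an [arc_segment()]), `theta`, `kappa`
#'   (canonical representation, see [canonical_arc()]), `score` (curvature
#'   NCC) and `refine` (the centre-refinement result).
#' @export
fit_membrane_curve <- function(avg, bank, angle_step = 2, length = NULL) {
  if (is.null(length)) length <- bank$length
  ro <- radon_orientation(avg, angle_step)
  ec <- estimate_curvature(avg, bank, ro$theta)
  can <- canonical_arc(ro$theta, ec$kappa)
  curve0 <- arc_segment(centre = ro$centre_offset, theta = can$theta,
                        kappa = can$kappa, length = length,
                        thickness = bank$spec$thickness)
  model <- render_arc(curve0, dim(avg$data), avg$pixel_size, bank$spec)
  rc <- tryCatch(
    refine_center(avg, model,
                  search_radius = min(50, min(dim(avg$data)) *
                                        avg$pixel_size / 4)),
    warning = function(w) list(dx = 0, dy = 0, ncc = NA, converged = FALSE))
  curve <- arc_segment(centre = curve0$centre + c(rc$dx, rc$dy),
                       theta = can$theta, kappa = can$kappa,
                       length = length, thickness = bank$spec$thickness)
  list(curve = curve, theta = can$theta, kappa = can$kappa,
       score = ec$score, refine = rc)
}

#' Canonical (theta, kappa) representation of an unoriented arc
#'
#' The pair (theta, kappa) and (theta + 180, -kappa) describe the same
#' unoriented membrane arc; with angles stored mod 180 this makes the sign
#' of kappa depend on the representative chosen. This helper folds the pair
#' to the representative with theta in (-90, 90], so estimates can be
#' compared to ground truth unambiguously.
#'
#' @param theta tangent angle, degrees.
#' @param kappa signed curvature, nm^-1.
#' @return list with `theta` in (-90, 90] and the correspondingly signed
#'   `kappa`.
#' @export
canonical_arc <- function(theta, kappa) {
  th <- theta %% 180
  if (th > 90) list(theta = th - 180, kappa = -kappa)
  else list(theta = th, kappa = kappa)
}

#' Shift an image by a physical translation
#'
#' Bilinear resampling; content moves by (+dx, +dy) in the physical frame,
#' zero fill at the borders.
#'
#' @param img a [mem_image()].
#' @param dx,dy translation in Å.
#' @return a [mem_image()].
#' @export
translate_image <- function(img, dx, dy) {
  g <- pixel_grid(dim(img$data), img$pixel_size)
  v <- bilinear_sample(img, as.vector(g$x) - dx, as.vector(g$y) - dy)
  mem_image(matrix(v, nrow(img$data), ncol(img$data)), img$pixel_size)
}
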