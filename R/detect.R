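#' Matched-filter template matching of bilayer side views
#'
#' Computes, for every pixel of a micrograph, the maximum normalized
#' cross-correlation over all bank templates rotated over theta in
#' [0, 180) degrees, together with the argmax orientation and curvature.
#' Correlation is evaluated in the frequency domain with local (windowed)
#' normalization over a circular support, so scores are invariant to global
#' affine intensity changes of the image and lie in [-1, 1].
#'
#' @param image a [mem_image()] micrograph.
#' @param bank a [template_bank()] (see [make_template_bank()]); its pixel
#'   size must match the image's within 2%.
#' @param angle_step rotation sampling step, degrees (default 5).
#' @return An object of class `match_field`: list with `score`, `theta`,
#'   `kappa` matrices (raster layout of `image`) and `pixel_size`.
#' @export
match_templates <- function(image, bank, angle_step = 5) {
  stopifnot(inherits(image, "mem_image"), inherits(bank, "template_bank"))
  rel <- abs(image$pixel_size - bank$pixel_size) / bank$pixel_size
  if (rel > 0.02)
    stop(sprintf("pixel-size mismatch: image %.4g vs bank %.4g Å/px (%.1f%% > 2%%)",
                 image$pixel_size, bank$pixel_size, 100 * rel))
  ny <- nrow(image$data); nx <- ncol(image$data)
  tsz <- nrow(bank$images[[1]]$data)
  if (tsz > min(ny, nx)) stop("templates larger than the image")
  prep <- ncc_prep(image$data, tsz / 2)
  angles <- seq(0, 180 - angle_step, by = angle_step)
  best <- matrix(-Inf, ny, nx); best_th <- matrix(0, ny, nx)
  best_k <- matrix(0, ny, nx)
  for (ti in seq_along(bank$images)) {
    tmpl <- bank$images[[ti]]
    for (th in angles) {
      rot <- if (th == 0) tmpl else rotate_image(tmpl, th)
      ncc <- ncc_apply(prep, rot$data)
      if (is.null(ncc)) next
      upd <- ncc > best
      if (any(upd)) {
        best[upd] <- ncc[upd]
        best_th[upd] <- th
        best_k[upd] <- bank$kappas[ti]
      }
    }
  }
  # correlation maps are computed with the template origin at [1, 1];
  # recentre so score[r, c] refers to a template centred near pixel (r, c).
  # With even raster sizes the template centre falls between pixels; the
  # residual sub-pixel offset is recorded for the picker.
  ctr_r <- floor(ny / 2) + 1L; ctr_c <- floor(nx / 2) + 1L
  er <- floor((ny - tsz) / 2) + (tsz + 1) / 2   # template centre row in frame
  ec <- floor((nx - tsz) / 2) + (tsz + 1) / 2
  off_r <- ((floor(ny / 2) + er - 1 + ny / 2) %% ny) - ny / 2
  off_c <- ((floor(nx / 2) + ec - 1 + nx / 2) %% nx) - nx / 2
  roll <- function(m) {
    r0 <- ((seq_len(ny) - 1 + (ctr_r - 1)) %% ny) + 1
    c0 <- ((seq_len(nx) - 1 + (ctr_c - 1)) %% nx) + 1
    m[r0, c0]
  }
  structure(list(score = roll(best), theta = roll(best_th),
                 kappa = roll(best_k), pixel_size = image$pixel_size,
                 centre_off_px = c(row = off_r, col = off_c)),
            class = "match_field")
}

# Precompute the image-side quantities of locally-normalized NCC:
# FFTs of the image and its square, and the local mean/power sums over a
# circular support of radius rad_px (Lewis' fast NCC with a disc window,
# which is rotation-invariant so one window serves all template rotations).
ncc_prep <- function(img_data, rad_px) {
  ny <- nrow(img_data); nx <- ncol(img_data)
  g <- pixel_grid(c(ny, nx), 1)
  mask <- (g$x^2 + g$y^2 <= rad_px^2) * 1
  n_mask <- sum(mask)
  Fi  <- stats::fft(img_data)
  Fi2 <- stats::fft(img_data^2)
  Fm  <- Conj(stats::fft(mask))
  loc_sum  <- Re(stats::fft(Fi  * Fm, inverse = TRUE)) / (ny * nx)
  loc_sum2 <- Re(stats::fft(Fi2 * Fm, inverse = TRUE)) / (ny * nx)
  denom_img <- sqrt(pmax(loc_sum2 - loc_sum^2 / n_mask, 0))
  list(ny = ny, nx = nx, mask = mask, n_mask = n_mask, Fi = Fi,
       denom_img = denom_img)
}

# NCC field of one template (small matrix) against a prepared image.
# Output indexing matches cross_correlate(); NULL for a degenerate template.
ncc_apply <- function(prep, tmpl_data) {
  emb <- embed_centred(tmpl_data, prep$ny, prep$nx) * prep$mask
  emb <- emb - prep$mask * sum(emb) / prep$n_mask    # zero mean in support
  tnorm <- sqrt(sum(emb^2))
  if (tnorm == 0) return(NULL)
  num <- Re(stats::fft(prep$Fi * Conj(stats::fft(emb)), inverse = TRUE)) /
    (prep$ny * prep$nx)
  ncc <- num / (prep$denom_img * tnorm)
  ncc[prep$denom_img < 1e-10 * tnorm] <- 0
  ncc
}

# Embed a small matrix centred in an ny x nx frame (zero padding).
embed_centred <- function(m, ny, nx) {
  out <- matrix(0, ny, nx)
  r0 <- floor((ny - nrow(m)) / 2)
  c0 <- floor((nx - ncol(m)) / 2)
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

#' Pick membrane segments from a template-matching score field
#'
#' Local maxima of the score field above `threshold` are accepted greedily
#' in descending score order with non-maximum suppression within
#' `nms_radius`. Ties in score are broken lexicographically on (row, col),
#' making the output deterministic.
#'
#' @param field a `match_field` from [match_templates()].
#' @param threshold minimum score in (0, 1); values above 1 never match.
#' @param nms_radius suppression radius, Å.
#' @return data.frame of picks: `centre_x_A`, `centre_y_A`, `theta_deg`,
#'   `kappa_per_nm`, `score`, ordered by descending score.
#' @export
pick_segments <- function(field, threshold = 0.4, nms_radius = 100) {
  stopifnot(inherits(field, "match_field"))
  if (threshold <= 0) stop("threshold must be in (0, 1]")
  s <- field$score
  ny <- nrow(s); nx <- ncol(s)
  # strict local maxima over the 8-neighbourhood (ties resolved towards
  # smaller (row, col) by using >= against later neighbours)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- s
  ge <- function(dr, dc) {
    nb <- pad[(2:(ny + 1)) + dr, (2:(nx + 1)) + dc]
    earlier <- dr < 0 | (dr == 0 & dc < 0)
    if (earlier) s > nb else s >= nb
  }
  is_max <- s >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & ge(dr, dc)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(centre_x_A = numeric(0), centre_y_A = numeric(0),
                      theta_deg = numeric(0), kappa_per_nm = numeric(0),
                      score = numeric(0)))
  sc <- s[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  r_px <- nms_radius / field$pixel_size
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1)])
    d2 <- (idx[i, 1] - idx[prev, 1])^2 + (idx[i, 2] - idx[prev, 2])^2
    keep[i] <- all(d2 > r_px^2)
  }
  idx <- idx[keep, , drop = FALSE]; sc <- sc[keep]
  off <- field$centre_off_px
  if (is.null(off)) off <- c(0, 0)
  xy <- rc_to_xy(idx[, 1] + off[1], idx[, 2] + off[2], c(ny, nx),
                 field$pixel_size)
  data.frame(centre_x_A = xy$x, centre_y_A = xy$y,
             theta_deg = field$theta[idx], kappa_per_nm = field$kappa[idx],
             score = sc)
}
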