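#' Sample membrane points from binarized density
#'
#' Returns the voxel centres (physical Å, centre-origin frame) whose density
#' is at least `threshold`, optionally excluding voxels under a protein
#' exclusion mask.
#'
#' @param volume a [mem_volume()].
#' @param threshold density threshold; must lie within the volume's value
#'   range.
#' @param exclusion_mask optional logical array of the volume's shape; TRUE
#'   voxels are excluded.
#' @return An object of class `point_cloud`: list with `points` (n x 3
#'   matrix, Å) and `source_threshold`.
#' @export
sample_membrane_points <- function(volume, threshold, exclusion_mask = NULL) {
  stopifnot(inherits(volume, "mem_volume"))
  rng <- range(volume$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("threshold %g outside the volume's value range [%g, %g]",
                 threshold, rng[1], rng[2]))
  keep <- volume$data >= threshold
  if (!is.null(exclusion_mask)) {
    stopifnot(all(dim(exclusion_mask) == dim(volume$data)))
    keep <- keep & !exclusion_mask
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) < 100)
    stop(sprintf("threshold too high: only %d voxels selected (>= 100 required)",
                 nrow(idx)))
  n <- dim(volume$data)
  ctr <- (n + 1) / 2
  pts <- sweep(idx, 2, ctr) * volume$voxel_size
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, source_threshold = threshold,
                 density = volume$data[keep]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud %d points, threshold %.4g>\n",
              nrow(x$points), x$source_threshold))
  invisible(x)
}

as_point_cloud <- function(points, threshold = NA_real_, density = NULL) {
  pts <- as.matrix(points)
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, source_threshold = threshold,
                 density = density),
            class = "point_cloud")
}

#' Total-least-squares reference plane of a point cloud
#'
#' Fits the plane minimizing orthogonal distances (smallest principal axis
#' of the centred covariance) and returns the rotation aligning the plane
#' normal with +z. The normal's sign is chosen so that the majority of an
#' optional marker point set ends up at z > 0; without markers, the sign
#' giving positive skewness of the out-of-plane coordinate is used (+z
#' towards the heavier tail of the point distribution), falling back to a
#' deterministic +z convention for symmetric clouds.
#'
#' @param cloud a `point_cloud`.
#' @param markers optional n x 3 matrix of "matrix-side" marker points, Å.
#' @return list with `normal` (unit length-3), `rotation` (3 x 3, maps the
#'   normal to +z), `centroid` (Å) and `rms` (orthogonal residual, Å).
#' @export
fit_reference_plane <- function(cloud, markers = NULL) {
  pts <- cloud$points
  if (nrow(pts) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  cv <- crossprod(X) / nrow(X)
  if (!all(is.finite(cv))) stop("rank-deficient covariance")
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1e-300))
    stop("degenerate (collinear) point cloud: plane is not defined")
  normal <- eg$vectors[, 3]
  if (!is.null(markers)) {
    side <- sweep(as.matrix(markers), 2, ctr) %*% normal
    if (mean(side > 0) < 0.5) normal <- -normal
  } else {
    r <- as.vector(X %*% normal)
    sk <- mean(r^3)
    if (abs(sk) > 1e-9 * stats::sd(r)^3) {
      if (sk < 0) normal <- -normal
    } else if (normal[3] < 0 ||
               (normal[3] == 0 && (normal[1] < 0 ||
                                   (normal[1] == 0 && normal[2] < 0)))) {
      normal <- -normal
    }
  }
  rotation <- rotation_to_z(normal)
  rms <- sqrt(mean((X %*% normal)^2))
  list(normal = normal, rotation = rotation, centroid = ctr, rms = rms)
}

# Rotation matrix mapping the unit vector v to +z (minimal rotation).
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Fit smooth leaflet surfaces to a bilayer point cloud
#'
#' Fits the bilayer mid-surface as a height field z(x, y) by local quadratic
#' (LOESS-style) regression with a Gaussian kernel, classifies points to the
#' upper/lower leaflet by the sign of their residual, and refits each
#' leaflet with the same smoother. The cloud must already be rotated so the
#' membrane normal is the z axis (see [fit_reference_plane()]). Grid nodes
#' with no point within `2 * bandwidth` are flagged missing (NA).
#'
#' @param cloud a `point_cloud` in the z-aligned frame.
#' @param thickness nominal head-to-head bilayer thickness, Å (default 40).
#' @param bandwidth kernel bandwidth of the local regression, Å (default
#'   30).
#' @param grid_spacing lateral grid spacing, Å (default 10).
#' @return An object of class `bilayer_surface`: list with `x`, `y` (axes,
#'   Å), `z_mid`, `z_upper`, `z_lower` (matrices, Å, NA = missing),
#'   `rotation` (the alignment rotation, recorded by the caller; identity
#'   by default), `thickness`, `grid_spacing`.
#' @export
fit_leaflet_surfaces <- function(cloud, thickness = 40, bandwidth = 30,
                                 grid_spacing = 10) {
  pts <- cloud$points
  # density values (when the cloud comes from a thresholded map) weight the
  # regression, recovering sub-voxel surface positions from the voxelized
  # shells
  wts <- cloud$density
  if (is.null(wts)) wts <- rep(1, nrow(pts))
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  xa <- seq(xr[1], xr[2], by = grid_spacing)
  ya <- seq(yr[1], yr[2], by = grid_spacing)
  z_mid <- local_quad_fit(pts, xa, ya, bandwidth, wts)
  # classify points by residual sign against the interpolated mid-surface
  zi <- grid_interp(xa, ya, z_mid, pts[, 1], pts[, 2])
  resid <- pts[, 3] - zi
  up <- resid >= 0 & !is.na(resid)
  lo <- resid < 0 & !is.na(resid)
  frac <- min(sum(up), sum(lo)) / max(nrow(pts), 1)
  sep <- mean(pts[up, 3] - zi[up], na.rm = TRUE) -
         mean(pts[lo, 3] - zi[lo], na.rm = TRUE)
  if (frac < 0.10 || (is.finite(sep) && sep < thickness / 4))
    warning(sprintf(
      "monolayer-like input: leaflet split %.0f%%, separation %.1f Å",
      100 * frac, sep))
  z_upper <- local_quad_fit(pts[up, , drop = FALSE], xa, ya, bandwidth,
                            wts[up])
  z_lower <- local_quad_fit(pts[lo, , drop = FALSE], xa, ya, bandwidth,
                            wts[lo])
  # enforce the leaflet ordering contract at noisy edge nodes
  z_upper <- pmax(z_upper, z_mid)
  z_lower <- pmin(z_lower, z_mid)
  structure(list(x = xa, y = ya, z_mid = z_mid, z_upper = z_upper,
                 z_lower = z_lower, rotation = diag(3),
                 thickness = thickness, grid_spacing = grid_spacing),
            class = "bilayer_surface")
}

#' @export
print.bilayer_surface <- function(x, ...) {
  cat(sprintf("<bilayer_surface %d x %d grid @ %.3g Å, %.0f%% sampled>\n",
              length(x$x), length(x$y), x$grid_spacing,
              100 * mean(!is.na(x$z_mid))))
  invisible(x)
}

# Local weighted quadratic regression of z on (x, y) at each grid node.
# points: n x 3 matrix. Returns matrix [ix, iy]; NA where no point lies
# within 2 * bandwidth.
local_quad_fit <- function(points, xa, ya, bandwidth, pw = NULL) {
  out <- matrix(NA_real_, length(xa), length(ya))
  if (nrow(points) == 0) return(out)
  if (is.null(pw)) pw <- rep(1, nrow(points))
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  r2max <- (2 * bandwidth)^2
  for (i in seq_along(xa)) {
    dx <- px - xa[i]
    sel_x <- abs(dx) <= 2 * bandwidth
    if (!any(sel_x)) next
    for (j in seq_along(ya)) {
      dy <- py - ya[j]
      sel <- sel_x & abs(dy) <= 2 * bandwidth
      if (!any(sel)) next
      dxs <- dx[sel]; dys <- dy[sel]
      r2 <- dxs^2 + dys^2
      ok <- r2 <= r2max
      if (!any(ok)) next
      dxs <- dxs[ok]; dys <- dys[ok]
      w <- exp(-r2[ok] / (2 * bandwidth^2)) * pw[sel][ok]
      z <- pz[sel][ok]
      if (length(z) >= 6) {
        A <- cbind(1, dxs, dys, dxs^2, dxs * dys, dys^2)
        fit <- tryCatch(stats::lm.wfit(A, z, w)$coefficients[1],
                        error = function(e) NA_real_)
        out[i, j] <- if (is.na(fit)) sum(w * z) / sum(w) else fit
      } else {
        out[i, j] <- sum(w * z) / sum(w)
      }
    }
  }
  out
}

# Bilinear interpolation of a grid field at scattered (x, y); NA outside.
grid_interp <- function(xa, ya, field, x, y) {
  dx <- xa[2] - xa[1]; dy <- ya[2] - ya[1]
  fi <- (x - xa[1]) / dx + 1
  fj <- (y - ya[1]) / dy + 1
  i0 <- floor(fi); j0 <- floor(fj)
  ok <- i0 >= 1 & i0 <= length(xa) - 1 & j0 >= 1 & j0 <= length(ya) - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  ii <- i0[ok]; jj <- j0[ok]
  ti <- fi[ok] - ii; tj <- fj[ok] - jj
  n1 <- nrow(field)
  k00 <- (jj - 1) * n1 + ii
  v <- (1 - ti) * (1 - tj) * field[k00] +
       ti       * (1 - tj) * field[k00 + 1] +
       (1 - ti) * tj       * field[k00 + n1] +
       ti       * tj       * field[k00 + n1 + 1]
  out[ok] <- v
  out
}

#' Gaussian smoothing of a fitted bilayer surface
#'
#' Filters each height field on the grid with an isotropic Gaussian of
#' standard deviation `sigma` (Å), normalized over non-missing nodes.
#' `sigma = 0` returns the model unchanged.
#'
#' @param model a `bilayer_surface`.
#' @param sigma Gaussian sigma, Å (>= 0).
#' @return a `bilayer_surface`.
#' @export
smooth_surface <- function(model, sigma) {
  stopifnot(inherits(model, "bilayer_surface"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(model)
  for (f in c("z_mid", "z_upper", "z_lower"))
    model[[f]] <- gauss_filter_na(model[[f]], sigma / model$grid_spacing)
  model
}

# Separable Gaussian filter with NA-aware (normalized) convolution.
gauss_filter_na <- function(m, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  w <- !is.na(m)
  m0 <- ifelse(w, m, 0)
  conv1 <- function(mat, kern, along) {
    n <- dim(mat)[along]
    out <- array(0, dim(mat))
    for (t in seq_along(kern)) {
      off <- t - half - 1L
      src <- seq_len(n) + off
      valid <- src >= 1 & src <= n
      if (!any(valid)) next
      if (along == 1) {
        out[valid, ] <- out[valid, ] + kern[t] * mat[src[valid], ]
      } else {
        out[, valid] <- out[, valid] + kern[t] * mat[, src[valid]]
      }
    }
    out
  }
  num <- conv1(conv1(m0, k, 1), k, 2)
  den <- conv1(conv1(w * 1, k, 1), k, 2)
  out <- num / den
  out[!w] <- NA_real_
  out[den < 1e-6] <- NA_real_
  out
}

#' Mean and Gaussian curvature of the fitted mid-surface
#'
#' Computes mean curvature H and Gaussian curvature K from the first and
#' second fundamental forms of the Monge patch z_mid(x, y), using central
#' finite differences, plus the altitude of the mid-surface relative to the
#' fitted reference plane (z = 0 after alignment). Sign convention: H > 0
#' where the surface is convex towards +z (the matrix side after
#' alignment). Nodes with missing neighbours are flagged NA.
#'
#' @param model a (smoothed) `bilayer_surface`.
#' @return An object of class `curvature_field`: list with `x`, `y`, `H`
#'   (nm^-1), `K` (nm^-2), `altitude` (Å).
#' @export
surface_curvature <- function(model) {
  stopifnot(inherits(model, "bilayer_surface"))
  z <- model$z_mid
  h <- model$grid_spacing
  nx <- nrow(z); ny <- ncol(z)
  ix <- 2:(nx - 1); iy <- 2:(ny - 1)
  fx <- fy <- fxx <- fyy <- fxy <- matrix(NA_real_, nx, ny)
  fx[ix, iy]  <- (z[ix + 1, iy] - z[ix - 1, iy]) / (2 * h)
  fy[ix, iy]  <- (z[ix, iy + 1] - z[ix, iy - 1]) / (2 * h)
  fxx[ix, iy] <- (z[ix + 1, iy] - 2 * z[ix, iy] + z[ix - 1, iy]) / h^2
  fyy[ix, iy] <- (z[ix, iy + 1] - 2 * z[ix, iy] + z[ix, iy - 1]) / h^2
  fxy[ix, iy] <- (z[ix + 1, iy + 1] - z[ix + 1, iy - 1] -
                  z[ix - 1, iy + 1] + z[ix - 1, iy - 1]) / (4 * h^2)
  g2 <- 1 + fx^2 + fy^2
  # graph-convention H is positive for a bowl opening towards +z; flip so
  # H > 0 means convex towards +z
  H_graph <- ((1 + fy^2) * fxx - 2 * fx * fy * fxy + (1 + fx^2) * fyy) /
    (2 * g2^1.5)
  H <- -H_graph * 10          # Å^-1 -> nm^-1
  K <- (fxx * fyy - fxy^2) / g2^2 * 100   # Å^-2 -> nm^-2
  structure(list(x = model$x, y = model$y, H = H, K = K,
                 altitude = z),
            class = "curvature_field")
}

#' Summary statistics of a curvature field over its well-supported interior
#'
#' Edge nodes of the fitted grid are supported by one-sided data and
#' truncated smoothing windows, which biases their height and curvature;
#' summaries therefore exclude a boundary margin (a fraction of the grid
#' span on each side) by default.
#'
#' @param field a `curvature_field` from [surface_curvature()].
#' @param trim fraction of the grid span excluded on each side (default
#'   0.15).
#' @return list with `H_median` (nm^-1), `K_median` (nm^-2), `n` nodes
#'   used.
#' @export
curvature_summary <- function(field, trim = 0.15) {
  nx <- length(field$x); ny <- length(field$y)
  ix <- seq_len(nx) > trim * nx & seq_len(nx) <= (1 - trim) * nx
  iy <- seq_len(ny) > trim * ny & seq_len(ny) <= (1 - trim) * ny
  H <- field$H[ix, iy]; K <- field$K[ix, iy]
  list(H_median = stats::median(H, na.rm = TRUE),
       K_median = stats::median(K, na.rm = TRUE),
       n = sum(!is.na(H)))
}

#' Generate a planar phospholipid bilayer pseudo-lattice
#'
#' Hexagonal lattice of lipid pseudo-atoms: phosphorus headgroup planes at
#' +/- thickness/2 and carbon tail pseudo-atoms between, used as the planar
#' structure that is deformed onto a fitted surface.
#'
#' @param extent lateral half-extent, Å.
#' @param spacing lattice spacing, Å (default 8).
#' @param thickness head-to-head thickness, Å (default 40).
#' @return a [structure_model()]; headgroup atoms have element `P`, tails
#'   `C`; the `resno` encodes the lattice site.
#' @export
make_planar_bilayer_lattice <- function(extent = 100, spacing = 8,
                                        thickness = 40) {
  rows <- seq(-extent, extent, by = spacing * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(-extent + off, extent, by = spacing)
    cbind(xs, rows[i])
  }))
  t2 <- thickness / 2
  deltas <- c(t2, t2 / 3, -t2 / 3, -t2)
  elems  <- c("P", "C", "C", "P")
  n <- nrow(pts)
  atoms <- do.call(rbind, lapply(seq_along(deltas), function(k) {
    data.frame(elem = elems[k],
               atom = if (elems[k] == "P") "P" else sprintf("C%d", k),
               resid = "LIP", resno = seq_len(n),
               chain = if (deltas[k] > 0) "U" else "L",
               x = pts[, 1], y = pts[, 2], z = deltas[k], occ = 1,
               stringsAsFactors = FALSE)
  }))
  structure_model(atoms)
}

#' Deform a planar bilayer lattice onto a fitted surface
#'
#' Maps each lattice atom at (x, y, delta) to the surface point
#' (x, y, z_mid(x, y)) displaced by delta along the local unit normal, so
#' headgroup pseudo-atoms at delta = +/- thickness/2 land on the leaflet
#' surfaces. Atoms whose lateral footprint leaves the fitted grid (or falls
#' on missing nodes) are dropped; the count is reported via a message and
#' the `dropped` attribute.
#'
#' @param lattice a [structure_model()] planar bilayer (z = offset from the
#'   bilayer mid-plane).
#' @param model a `bilayer_surface`.
#' @return the deformed [structure_model()] with attribute `dropped`.
#' @export
deform_planar_bilayer <- function(lattice, model) {
  stopifnot(inherits(lattice, "mem_structure"),
            inherits(model, "bilayer_surface"))
  zmax <- max(abs(lattice$z))
  if (zmax > model$thickness)
    stop("lattice z-extent exceeds the bilayer thickness")
  x <- lattice$x; y <- lattice$y; delta <- lattice$z
  zm <- grid_interp(model$x, model$y, model$z_mid, x, y)
  h <- model$grid_spacing
  # gradient by symmetric finite differences of the interpolated field
  gx <- (grid_interp(model$x, model$y, model$z_mid, x + h / 2, y) -
         grid_interp(model$x, model$y, model$z_mid, x - h / 2, y)) / h
  gy <- (grid_interp(model$x, model$y, model$z_mid, x, y + h / 2) -
         grid_interp(model$x, model$y, model$z_mid, x, y - h / 2)) / h
  ok <- !is.na(zm) & !is.na(gx) & !is.na(gy)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("deform_planar_bilayer: dropped %d atoms outside the fitted grid",
                    dropped))
  norm <- sqrt(1 + gx[ok]^2 + gy[ok]^2)
  out <- lattice[ok, , drop = FALSE]
  out$x <- x[ok] + delta[ok] * (-gx[ok] / norm)
  out$y <- y[ok] + delta[ok] * (-gy[ok] / norm)
  out$z <- zm[ok] + delta[ok] / norm
  class(out) <- c("mem_structure", "data.frame")
  attr(out, "dropped") <- dropped
  out
}
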