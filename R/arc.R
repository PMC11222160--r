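#' Parametric membrane arc segment
#'
#' A bilayer membrane seen side-on in a 2D image is modelled as a single
#' circular arc: centre position, tangent angle at the centre, signed
#' curvature, arc length and bilayer thickness. Curvature follows the
#' convention that kappa > 0 bends the membrane towards local "up" (+y after
#' rotating the tangent to horizontal). Angles are stored modulo 180 degrees
#' because a membrane line is unoriented.
#'
#' @param centre numeric length-2, (x, y) in Å in the host image frame.
#' @param theta tangent angle at the centre, degrees (stored mod 180).
#' @param kappa signed curvature, nm^-1.
#' @param length arc length, Å.
#' @param thickness bilayer head-to-head thickness, Å.
#' @return An object of class `arc_segment`.
#' @export
arc_segment <- function(centre = c(0, 0), theta = 0, kappa = 0,
                        length = 300, thickness = 40) {
  stopifnot(length(centre) == 2, is.finite(centre))
  if (length <= 0) stop("length must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  # folding theta by 180 degrees reverses the tangent and hence the local
  # normal; flip kappa when an odd number of folds is applied so the stored
  # pair describes the same geometry the caller specified
  theta <- as.numeric(theta)
  kappa <- as.numeric(kappa)
  if (floor(theta / 180) %% 2 != 0) kappa <- -kappa
  structure(list(centre = as.numeric(centre),
                 theta = theta %% 180,
                 kappa = kappa,
                 length = as.numeric(length),
                 thickness = as.numeric(thickness)),
            class = "arc_segment")
}

#' @export
print.arc_segment <- function(x, ...) {
  cat(sprintf(
    "<arc_segment centre=(%.1f, %.1f) Å, theta=%.2f°, kappa=%.4f nm^-1, length=%.0f Å>\n",
    x$centre[1], x$centre[2], x$theta, x$kappa, x$length))
  invisible(x)
}

#' 2D alignment parameters
#'
#' Rigid (plus optional mirror) transform used to carry a fitted membrane
#' curve from a class-average frame into a raw-image frame. The transform is
#' applied as: mirror about the x axis (if requested), then rotation
#' counter-clockwise, then translation.
#'
#' @param rotation degrees, counter-clockwise.
#' @param shift numeric length-2, (dx, dy) in Å.
#' @param mirror logical; mirror about the horizontal axis before rotating.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(rotation = 0, shift = c(0, 0), mirror = FALSE) {
  stopifnot(length(shift) == 2)
  structure(list(rotation = as.numeric(rotation),
                 shift = as.numeric(shift),
                 mirror = isTRUE(mirror)),
            class = "alignment_params")
}

#' Invert alignment parameters
#'
#' @param align an [alignment_params()].
#' @return the inverse transform, also an [alignment_params()].
#' @export
invert_alignment <- function(align) {
  a <- align$rotation * pi / 180
  # forward: p' = R M p + t  =>  inverse: p = M R^T (p' - t)
  # expressed in the same mirror-rotate-translate form:
  # M R^T (p' - t) = (M R^T M) M p' - M R^T t ; M R^T M is rotation by
  # +rotation when mirrored, -rotation otherwise.
  rot_inv <- if (align$mirror) align$rotation else -align$rotation
  t <- align$shift
  Rt <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # R^T (row-major)
  v <- -as.vector(Rt %*% t)
  if (align$mirror) v[2] <- -v[2]
  alignment_params(rotation = rot_inv, shift = v, mirror = align$mirror)
}

#' Apply alignment parameters to a membrane curve
#'
#' Rigidly transforms an [arc_segment()]: the centre is mirrored (optional),
#' rotated and shifted; the tangent angle follows the rotation (mod 180);
#' curvature magnitude and arc length are preserved, and mirroring flips the
#' curvature sign.
#'
#' @param curve an [arc_segment()].
#' @param align an [alignment_params()].
#' @return the transformed [arc_segment()].
#' @export
transform_curve <- function(curve, align) {
  stopifnot(inherits(curve, "arc_segment"), inherits(align, "alignment_params"))
  p <- curve$centre
  th <- curve$theta
  k <- curve$kappa
  if (align$mirror) {
    p[2] <- -p[2]
    th <- -th
    k <- -k
  }
  a <- align$rotation * pi / 180
  p2 <- c(cos(a) * p[1] - sin(a) * p[2],
          sin(a) * p[1] + cos(a) * p[2]) + align$shift
  arc_segment(centre = p2, theta = th + align$rotation,
              kappa = k, length = curve$length, thickness = curve$thickness)
}

# Curvilinear coordinates of physical points relative to an arc.
# Returns list(n, s): signed normal offset (Å, +n towards the side the
# membrane bends to for kappa > 0) and arc length from the segment centre
# (Å, increasing along the tangent direction).
arc_coords <- function(x, y, curve) {
  th <- curve$theta * pi / 180
  dx <- x - curve$centre[1]
  dy <- y - curve$centre[2]
  u <- cos(th) * dx + sin(th) * dy
  w <- -sin(th) * dx + cos(th) * dy
  k_A <- curve$kappa / 10  # nm^-1 -> Å^-1
  if (abs(k_A) < 1e-9) return(list(n = w, s = u))
  R <- 1 / k_A                         # signed radius, Å
  sig <- sign(R)
  du <- u
  dw <- w - R
  d <- sqrt(du^2 + dw^2)
  n <- sig * (abs(R) - d)
  # signed angle from the centre->midpoint direction r0 = (0, -sig)
  # (CCW positive); s = R * angle so s increases along +u for either sign.
  vx <- du / d; vy <- dw / d
  dot <- -sig * vy
  crs <- sig * vx                      # r0.x*vy - r0.y*vx with r0 = (0,-sig)
  ang <- atan2(crs, dot)
  list(n = n, s = R * ang)
}

# Inverse mapping: physical (x, y) position of curvilinear (s, n) points.
arc_point <- function(curve, s, n) {
  k_A <- curve$kappa / 10
  if (abs(k_A) < 1e-9) {
    u <- s; w <- n
  } else {
    R <- 1 / k_A
    sig <- sign(R)
    alpha <- s / R
    # unit radial direction, rotated CCW by alpha from r0 = (0, -sig)
    rx <- sig * sin(alpha)
    ry <- -sig * cos(alpha)
    fac <- abs(R) - sig * n
    u <- fac * rx
    w <- R + fac * ry
  }
  th <- curve$theta * pi / 180
  list(x = curve$centre[1] + cos(th) * u - sin(th) * w,
       y = curve$centre[2] + sin(th) * u + cos(th) * w)
}
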