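# Pixel scale along the disparity axis: signed pixels per unit tangent.
pixel_scale <- function(intr) (intr$y0 / 2) / tan(deg2rad(intr$phi0 / 2))

#' Convert a signed pixel coordinate to a ray tangent
#'
#' The pinhole mapping along the disparity axis:
#' `tan(phi) = y * tan(phi0/2) / (y0/2)`, sign preserved. The inverse is
#' [tangent_to_pixel()].
#'
#' @param y signed pixel coordinate(s), origin at the image center;
#'   `|y| <= y0/2`.
#' @param intr a [camera_intrinsics()].
#' @return dimensionless tangent ratio(s), same length as `y`.
#' @examples
#' intr <- camera_intrinsics()
#' pixel_to_tangent(0, intr)            # optical axis
#' pixel_to_tangent(intr$y0 / 2, intr)  # FoV edge: tan(phi0/2)
#' @export
pixel_to_tangent <- function(y, intr) {
  if (any(abs(y) > intr$y0 / 2)) {
    stop("pixel coordinate outside the sensor: |y| > y0/2")
  }
  y / pixel_scale(intr)
}

#' @rdname pixel_to_tangent
#' @param tangent dimensionless tangent ratio(s).
#' @export
tangent_to_pixel <- function(tangent, intr) tangent * pixel_scale(intr)

#' Quantize real-valued pixels to the integer grid
#'
#' Round-half-away-from-zero to the nearest integer pixel; when an
#' intrinsics context is supplied the result is clipped to `[-y0/2, y0/2]`.
#'
#' @param y real-valued signed pixel coordinate(s).
#' @param intr optional [camera_intrinsics()] supplying the clipping range.
#' @return integer-valued pixels.
#' @examples
#' quantize_pixels(c(0.4, -0.5, 100.5))
#' @export
quantize_pixels <- function(y, intr = NULL) {
  q <- round_half_away(y)
  if (!is.null(intr)) q <- pmin(pmax(q, -intr$y0 / 2), intr$y0 / 2)
  q
}

#' Project a world position into both cameras
#'
#' Forward pinhole model of the rotated-axes rig. Positions are given in the
#' rig frame of camera C1: `D` is the distance to the object plane
#' (perpendicular to the optical axes) and `lateral` the signed offset from
#' C1's optical axis, positive toward C2's axis. Substituting the returned
#' real-valued pixels into [triangulate_distance()] recovers `D` exactly.
#'
#' @param D distance(s) to the object plane in m, `> 0` and
#'   `D + B*sin(alpha) > 0`.
#' @param lateral signed lateral offset(s) from C1's optical axis in m.
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @return a data.frame with real-valued pixels `y1`, `y2`, a logical
#'   `in_fov` flag (both projections within `[-y0/2, y0/2]`), and the
#'   triangulation intermediates `Db`, `Dk`, `b0`, `b1`, `b2`, `d1`, `d2`
#'   (`b1 + b2 = B*cos(alpha)`, `d1 + d2 = B*sin(alpha)`, `Dk = D`).
#' @examples
#' fp <- forward_project(7.021, 0.31, rig_geometry(), camera_intrinsics())
#' fp$y1 - fp$y2 # disparity
#' @export
forward_project <- function(D, lateral, rig, intr) {
  if (any(D <= 0)) stop("D must be positive")
  a <- deg2rad(rig$alpha)
  Bc <- rig$B * cos(a)
  Bs <- rig$B * sin(a)
  if (any(D + Bs <= 0)) stop("D + B*sin(alpha) must be positive")
  k <- pixel_scale(intr)
  y1 <- k * lateral / D
  y2 <- k * (lateral - Bc) / (D + Bs)
  half <- intr$y0 / 2
  # intermediates of the geometric construction (see triangulation docs)
  d1 <- lateral * tan(a)
  data.frame(
    y1 = y1, y2 = y2,
    in_fov = abs(y1) <= half & abs(y2) <= half,
    Db = D + d1, Dk = D,
    b0 = if (Bc > 0) lateral * rig$B / Bc else 0,
    b1 = lateral, b2 = Bc - lateral,
    d1 = d1, d2 = Bs - d1)
}

#' Distance for the classical (alpha = 0) stereo configuration
#'
#' `D = B * y0 / (2 * tan(phi0/2) * disparity)`, the classical limit of the
#' rotated-axes formula.
#'
#' @param disparity pixel difference(s) `y1 - y2`, `>= 1`.
#' @param B baseline length in m.
#' @param intr a [camera_intrinsics()].
#' @return distance(s) in m.
#' @examples
#' classical_distance(720, 1, camera_intrinsics())
#' @export
classical_distance <- function(disparity, B, intr) {
  if (any(disparity <= 0)) {
    stop("non-triangulable: disparity must be >= 1 pixel")
  }
  B * intr$y0 / (2 * tan(deg2rad(intr$phi0 / 2)) * disparity)
}

#' Triangulate distance and altitude from a paired pixel observation
#'
#' Closed-form triangulation under the rotated-axes geometry. The distance
#' is computed along two algebraically equivalent routes -- directly from
#' pixels,
#' `D = B*cos(a)*y0 / (2*tan(phi0/2)*(y1-y2)) + B*sin(a)*y2/(y1-y2)`,
#' and from the ray angles
#' `D = B*(cos(a) - sin(a)*tan(phi2)) / (tan(phi1) + tan(phi2))` with
#' `tan(phi1) = y1*tan(phi0/2)/(y0/2)` and `tan(phi2) = -y2*tan(phi0/2)/(y0/2)`
#' -- and agreement to machine tolerance is asserted on every call. The
#' altitude is filled from [altitude_from_ray()] (the self-consistent
#' inverse of [forward_project()]); the literal textbook formula is also
#' available as [altitude_eq10()].
#'
#' @param obs a data.frame of observations with at least columns `y1`, `y2`
#'   (signed center-origin pixels), e.g. from [pair_stereo()] or
#'   [read_observations()].
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @return a data.frame (one row per observation) with columns `D` (m), `H`
#'   (altitude above ground, m), `dD` (quantization uncertainty of `D`, m,
#'   equal to `D/(y1 - y2)`), and signed ray angles `phi1`, `phi2`
#'   (degrees).
#' @examples
#' obs <- data.frame(y1 = 100, y2 = -100)
#' triangulate_distance(obs, rig_geometry(), camera_intrinsics())
#' @export
triangulate_distance <- function(obs, rig, intr) {
  y1 <- obs$y1
  y2 <- obs$y2
  if (is.null(y1) || is.null(y2)) stop("obs must have columns y1 and y2")
  disparity <- y1 - y2
  if (any(disparity < 1)) {
    stop("non-triangulable observation: disparity (y1 - y2) < 1 pixel")
  }
  a <- deg2rad(rig$alpha)
  t0 <- tan(deg2rad(intr$phi0 / 2))
  # route 1: pixels
  D8 <- rig$B * cos(a) * intr$y0 / (2 * t0 * disparity) +
    rig$B * sin(a) * y2 / disparity
  # route 2: ray angles
  tan1 <- pixel_to_tangent(y1, intr)
  tan2 <- -pixel_to_tangent(y2, intr)
  D5 <- rig$B * (cos(a) - sin(a) * tan2) / (tan1 + tan2)
  rel <- abs(D5 - D8) / pmax(abs(D8), .Machine$double.eps)
  stopifnot("angle- and pixel-route distances disagree" = all(rel < 1e-9))
  loc <- data.frame(
    D = D8,
    H = NA_real_,
    dD = D8 / disparity,
    phi1 = rad2deg(atan(tan1)),
    phi2 = rad2deg(atan(tan2)))
  loc$H <- altitude_from_ray(loc, obs, rig, intr)
  loc
}

#' Altitude from the literal cotangent formula
#'
#' `H = D * cot(phi0/2 + phi2)`: the printed closed form, which references
#' neither the rotation angle nor the mount height. Its angle convention
#' cannot be reconciled unambiguously with the rig geometry, so the
#' geometry-consistent [altitude_from_ray()] is provided alongside; this
#' function implements the formula exactly as stated.
#'
#' @param D distance(s) in m.
#' @param phi2 signed ray angle(s) in camera C2, degrees (e.g. from
#'   [triangulate_distance()]).
#' @param intr a [camera_intrinsics()].
#' @return altitude(s) in m.
#' @examples
#' altitude_eq10(100, 10, camera_intrinsics())
#' @export
altitude_eq10 <- function(D, phi2, intr) {
  ang <- intr$phi0 / 2 + phi2
  if (any(ang <= 0 | ang >= 180)) {
    stop("degenerate ray: phi0/2 + phi2 must lie strictly inside (0, 180)")
  }
  D / tan(deg2rad(ang))
}

#' Altitude by intersecting the camera rays with the object plane
#'
#' Geometry-consistent altitude: the object plane at distance `D` is
#' intersected with the C1 ray (the C2 ray gives the identical point), and
#' the world height of the intersection above ground is returned. With
#' real-valued (unquantized) pixels this inverts [forward_project()]
#' exactly.
#'
#' @param loc a data.frame with column `D` (m), e.g. from
#'   [triangulate_distance()].
#' @param obs the matching observations with column `y1`.
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @return altitude(s) above ground in m.
#' @examples
#' rig <- rig_geometry(); intr <- camera_intrinsics()
#' fp <- forward_project(150, lateral_from_altitude(150, 40, rig), rig, intr)
#' loc <- triangulate_distance(fp, rig, intr)
#' loc$H # 40, round trip
#' @export
altitude_from_ray <- function(loc, obs, rig, intr) {
  lateral <- loc$D * pixel_to_tangent(obs$y1, intr)
  altitude_from_lateral(loc$D, lateral, rig)
}

#' Convert between altitude and lateral offset at a given distance
#'
#' The rig frame (C1 upper camera, axes elevated `alpha` above horizontal,
#' lateral positive downward) relates world altitude `H` and the lateral
#' offset `L` at object-plane distance `D` by
#' `H = mount_height + D*sin(alpha) - L*cos(alpha)`.
#'
#' @param D distance(s) to the object plane in m.
#' @param H altitude(s) above ground in m.
#' @param lateral signed lateral offset(s) in m.
#' @param rig a [rig_geometry()].
#' @return `lateral_from_altitude()` returns lateral offsets in m;
#'   `altitude_from_lateral()` returns altitudes in m.
#' @examples
#' rig <- rig_geometry()
#' altitude_from_lateral(100, lateral_from_altitude(100, 30, rig), rig)
#' @export
lateral_from_altitude <- function(D, H, rig) {
  a <- deg2rad(rig$alpha)
  (rig$mount_height + D * sin(a) - H) / cos(a)
}

#' @rdname lateral_from_altitude
#' @export
altitude_from_lateral <- function(D, lateral, rig) {
  a <- deg2rad(rig$alpha)
  rig$mount_height + D * sin(a) - lateral * cos(a)
}
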