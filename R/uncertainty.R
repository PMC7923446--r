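#' Quantization uncertainty of the triangulated distance
#'
#' One quantization step of the discrete distance function, obtained by the
#' exact-differential method:
#' `dD = (y0*cos(a)/(2*tan(phi0/2)) + y2*sin(a)) * B / (y1 - y2)^2`,
#' which is algebraically identical to `D / (y1 - y2)`; the identity is
#' asserted on every call. For `alpha > 0` the uncertainty grows not only
#' with distance but also with the object's position `y2` on the C2 image
#' plane.
#'
#' @param obs a data.frame with columns `y1`, `y2` (signed center-origin
#'   pixels), disparity `y1 - y2 >= 1`.
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @return uncertainty value(s) in m.
#' @examples
#' quantization_uncertainty(data.frame(y1 = 100, y2 = -100),
#'                          rig_geometry(), camera_intrinsics())
#' @export
quantization_uncertainty <- function(obs, rig, intr) {
  disparity <- obs$y1 - obs$y2
  if (any(disparity < 1)) {
    stop("non-triangulable observation: disparity (y1 - y2) < 1 pixel")
  }
  a <- deg2rad(rig$alpha)
  dD <- (intr$y0 * cos(a) / (2 * tan(deg2rad(intr$phi0 / 2))) +
           obs$y2 * sin(a)) * rig$B / disparity^2
  D <- triangulate_distance(obs[c("y1", "y2")], rig, intr)$D
  stopifnot("differential and D/(y1-y2) forms disagree" =
              all(abs(dD - D / disparity) <=
                    1e-9 * pmax(abs(dD), .Machine$double.eps)))
  dD
}

#' Distance and uncertainty surface over the integer pixel grid
#'
#' Evaluates the triangulated distance `D` and its quantization uncertainty
#' `dD` on the integer grid of disparities and `y2` values, keeping cells
#' with `0 < D <= max_range`. Reproduces the characteristic surfaces of the
#' modified geometry: at fixed disparity, `dD` increases with `y2` when
#' `alpha > 0` and is constant across `y2` when `alpha = 0`.
#'
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @param max_range keep only grid cells with `D <= max_range` (m).
#' @param y2_step stride through the integer `y2` grid (default 1; use a
#'   larger stride for coarse plots).
#' @return an object of class `uncertainty_surface`: a data.frame in long
#'   format with columns `disparity`, `y2`, `D`, `dD`.
#' @examples
#' surf <- uncertainty_surface(rig_geometry(), camera_intrinsics(),
#'                             max_range = 50, y2_step = 90)
#' max(surf$dD)
#' @export
uncertainty_surface <- function(rig, intr, max_range, y2_step = 1) {
  if (max_range <= 0) stop("max_range must be positive")
  half <- intr$y0 / 2
  a <- deg2rad(rig$alpha)
  num0 <- rig$B * cos(a) * intr$y0 / (2 * tan(deg2rad(intr$phi0 / 2)))
  Bs <- rig$B * sin(a)
  y2 <- seq(-half, half, by = y2_step)
  # smallest disparity that can still satisfy D <= max_range for some y2
  dmin <- max(1, floor(min((num0 + Bs * y2) / max_range)))
  disparity <- seq(dmin, intr$y0, by = 1)
  grid <- expand.grid(disparity = disparity, y2 = y2)
  grid$D <- (num0 + Bs * grid$y2) / grid$disparity
  grid$dD <- grid$D / grid$disparity
  grid <- grid[grid$D > 0 & grid$D <= max_range, , drop = FALSE]
  rownames(grid) <- NULL
  class(grid) <- c("uncertainty_surface", "data.frame")
  grid
}

#' Baseline selection sweep
#'
#' For each candidate baseline, reports the worst-case quantization
#' uncertainty at the range limit for both extreme object positions on the
#' C2 image plane (`y2 = -y0/2` and `+y0/2`; the bottom and top of the
#' sensor in the center-origin convention). `min_disparity` is the smallest
#' integer disparity whose distance does not exceed the range limit, `dD` is
#' the uncertainty at that disparity, and `dD_continuous` the uncertainty of
#' an object exactly at the range limit (`= range^2 / (B*cos(a)*y0 /
#' (2*tan(phi0/2)) + B*sin(a)*y2)`, proportional to `1/B` at fixed range).
#' Supports the selection rule "smallest B whose statistic meets a target".
#'
#' @param candidates baseline lengths in m, all positive.
#' @param range_limit system range limit in m.
#' @param rig_template a [rig_geometry()] supplying `alpha` and mount
#'   height; the baseline is swept.
#' @param intr a [camera_intrinsics()].
#' @param y2_extremes the two `y2` values treated as worst-case object
#'   positions (default `c(-y0/2, y0/2)`).
#' @return a data.frame with one row per (candidate, extreme): columns `B`,
#'   `y2`, `min_disparity`, `D_at_min_disparity`, `dD`, `dD_continuous`,
#'   `reachable` (FALSE when no integer disparity puts the distance within
#'   the range limit).
#' @examples
#' baseline_sweep(c(0.75, 1, 1.25, 1.5), 300,
#'                rig_geometry(), camera_intrinsics())
#' @export
baseline_sweep <- function(candidates, range_limit, rig_template, intr,
                           y2_extremes = c(-intr$y0 / 2, intr$y0 / 2)) {
  if (length(candidates) == 0 || any(candidates <= 0)) {
    stop("candidates must be a non-empty vector of positive baselines")
  }
  if (range_limit <= 0) stop("range_limit must be positive")
  a <- deg2rad(rig_template$alpha)
  t0 <- tan(deg2rad(intr$phi0 / 2))
  rows <- expand.grid(B = candidates, y2 = y2_extremes)
  num <- rows$B * (cos(a) * intr$y0 / (2 * t0) + sin(a) * rows$y2)
  # D(disparity) = num / disparity, decreasing in disparity
  s <- num / range_limit                 # continuous disparity at the limit
  # physical disparity cannot exceed the sensor extent y0
  rows$min_disparity <- pmin(pmax(1, ceiling(s - 1e-12)), intr$y0)
  rows$D_at_min_disparity <- num / rows$min_disparity
  rows$dD <- rows$D_at_min_disparity / rows$min_disparity
  rows$dD_continuous <- range_limit^2 / num
  rows$reachable <- num > 0 & rows$D_at_min_disparity <= range_limit + 1e-9
  rows
}

#' Quantization uncertainty of a metric size measure
#'
#' Exact differential of the pixel-to-metric size mapping
#' `PW = D * pW * SIA / (f * y0)` with a one-pixel width quantum:
#' `dPW = (SIA / (f * y0)) * (pW * dD + D * dpW)`. Used to draw the
#' class-separation bands of wingspan versus distance.
#'
#' @param D distance(s) in m.
#' @param dD distance uncertainty(ies) in m, e.g. from
#'   [quantization_uncertainty()].
#' @param pW measured pixel width(s).
#' @param intr a [camera_intrinsics()].
#' @param dpW pixel-width quantum (default 1 px).
#' @return size uncertainty(ies) in m.
#' @examples
#' size_measure_uncertainty(100, 0, 14, camera_intrinsics()) # single-pixel term
#' @export
size_measure_uncertainty <- function(D, dD, pW, intr, dpW = 1) {
  if (any(D <= 0)) stop("D must be positive")
  (intr$sia / (intr$f * intr$y0)) * (pW * dD + D * dpW)
}
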