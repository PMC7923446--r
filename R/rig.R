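#' Camera intrinsics
#'
#' Intrinsic parameters of one camera of the stereo pair. Only the axis
#' aligned with the baseline (the vertical image axis of the vertically
#' mounted rig) enters the triangulation model; the horizontal axis is kept
#' for rendering and for the lateral (third) coordinate.
#'
#' @param y0 vertical resolution in pixels along the disparity axis; must be
#'   a positive even count so the center-origin pixel convention is well
#'   defined.
#' @param phi0 vertical field of view in degrees, in (0, 180).
#' @param f focal length in mm.
#' @param sia sensor image dimension along the disparity axis in mm (for the
#'   Sony IMX219 used as the reference sensor, 3.76 mm).
#' @param x0 horizontal resolution in pixels; used only by the renderer and
#'   the horizontal centroid mapping (default 1080).
#' @return an object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics() # the reference configuration: 1440 px, 48.8 deg, f=3
#' @export
camera_intrinsics <- function(y0 = 1440, phi0 = 48.8, f = 3, sia = 3.76,
                              x0 = 1080) {
  stop_if_not_scalar(y0, "y0"); stop_if_not_scalar(phi0, "phi0")
  stop_if_not_scalar(f, "f"); stop_if_not_scalar(sia, "sia")
  stop_if_not_scalar(x0, "x0")
  if (y0 <= 0 || y0 %% 2 != 0) stop("y0 must be a positive even pixel count")
  if (phi0 <= 0 || phi0 >= 180) stop("phi0 must lie in (0, 180) degrees")
  if (f <= 0) stop("focal length f must be positive")
  if (sia <= 0) stop("sensor dimension sia must be positive")
  if (x0 <= 0) stop("x0 must be a positive pixel count")
  structure(list(y0 = y0, phi0 = phi0, f = f, sia = sia, x0 = x0),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "camera_intrinsics: y0 = %g px, phi0 = %g deg, f = %g mm, SIA = %g mm, x0 = %g px\n",
    x$y0, x$phi0, x$f, x$sia, x$x0))
  invisible(x)
}

#' Stereo rig geometry
#'
#' Baseline length and common rotation angle of the stereo pair. `alpha` is
#' measured from the perpendicular to the baseline, so `alpha = 0` is the
#' classical configuration with both optical axes perpendicular to the
#' baseline. C1 is the upper camera; C2 is mounted `B` below it.
#'
#' @param B baseline length in m (> 0).
#' @param alpha rotation angle of both (parallel) optical axes in degrees,
#'   in `[0, 90)`. The reference rig uses `alpha = phi0/2 = 24.4`.
#' @param mount_height height of camera C1 above ground in m (default 0).
#' @return an object of class `rig_geometry`.
#' @examples
#' rig_geometry()               # B = 1 m, alpha = 24.4 deg
#' rig_geometry(B = 1, alpha = 0) # classical stereovision
#' @export
rig_geometry <- function(B = 1, alpha = 24.4, mount_height = 0) {
  stop_if_not_scalar(B, "B"); stop_if_not_scalar(alpha, "alpha")
  stop_if_not_scalar(mount_height, "mount_height")
  if (B <= 0) stop("baseline B must be positive")
  if (alpha < 0 || alpha >= 90) stop("alpha must lie in [0, 90) degrees")
  structure(list(B = B, alpha = alpha, mount_height = mount_height),
            class = "rig_geometry")
}

#' @export
print.rig_geometry <- function(x, ...) {
  cat(sprintf("rig_geometry: B = %g m, alpha = %g deg, mount height = %g m\n",
              x$B, x$alpha, x$mount_height))
  invisible(x)
}

#' Read or write a rig/camera configuration file
#'
#' YAML configuration with keys `baseline_m`, `alpha_deg`, `y0_px`,
#' `fov_deg`, `focal_mm`, `sia_mm`, `mount_height_m` and optionally
#' `x0_px`.
#'
#' @param path path to a YAML file.
#' @return `read_rig_config()` returns `list(rig, intrinsics)`;
#'   `write_rig_config()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_rig_config(path, rig_geometry(), camera_intrinsics())
#' cfg <- read_rig_config(path)
#' cfg$rig
#' @export
read_rig_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("baseline_m", "alpha_deg", "y0_px", "fov_deg", "focal_mm", "sia_mm")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("rig config is missing keys: ", paste(missing, collapse = ", "))
  }
  rig <- rig_geometry(B = cfg$baseline_m, alpha = cfg$alpha_deg,
                      mount_height = cfg$mount_height_m %||% 0)
  intr <- camera_intrinsics(y0 = cfg$y0_px, phi0 = cfg$fov_deg,
                            f = cfg$focal_mm, sia = cfg$sia_mm,
                            x0 = cfg$x0_px %||% 1080)
  list(rig = rig, intrinsics = intr)
}

#' @rdname read_rig_config
#' @param rig a [rig_geometry()].
#' @param intrinsics a [camera_intrinsics()].
#' @export
write_rig_config <- function(path, rig, intrinsics) {
  yaml::write_yaml(list(
    baseline_m = rig$B, alpha_deg = rig$alpha,
    mount_height_m = rig$mount_height,
    y0_px = intrinsics$y0, fov_deg = intrinsics$phi0,
    focal_mm = intrinsics$f, sia_mm = intrinsics$sia,
    x0_px = intrinsics$x0), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
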