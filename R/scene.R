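#' Target specification
#'
#' Metric dimensions of a simulated flying target (drone or bird surrogate).
#'
#' @param wingspan wingspan in m (> 0).
#' @param height body height in m (> 0).
#' @param label nominal size class, one of `"small"`, `"medium"`,
#'   `"large"`.
#' @return an object of class `target_spec`.
#' @examples
#' target_spec(1.20, 0.53, "medium")
#' @export
target_spec <- function(wingspan, height, label = c("small", "medium", "large")) {
  label <- match.arg(label)
  if (wingspan <= 0 || height <= 0) stop("target dimensions must be positive")
  structure(list(wingspan = wingspan, height = height, label = label),
            class = "target_spec")
}

smooth_jitter <- function(n, sd_target, fps) {
  if (sd_target <= 0 || n < 2) return(numeric(n))
  w <- max(1, round(fps))
  z <- stats::filter(stats::rnorm(n), rep(1 / w, w), circular = TRUE)
  z <- as.numeric(z)
  # standardize so the realized sd is exactly the requested one
  (z - mean(z)) / stats::sd(z) * sd_target
}

#' Generate a synthetic flight trajectory
#'
#' Emulates the validation flights: near-constant distance and altitude
#' orbits around the rig. Distance and altitude are mean values plus
#' smoothed Gaussian jitter (white noise low-passed over a one-second
#' moving window, then standardized so the realized standard deviation
#' equals the requested one). The lateral (horizontal) coordinate is the
#' in-view chord of the orbit: a constant-speed crossing through the image
#' center at mid-flight.
#'
#' @param mean_D mean distance to the object plane in m.
#' @param mean_H mean altitude in m.
#' @param speed horizontal speed in m/s.
#' @param duration flight duration in s.
#' @param jitter_sd numeric pair: standard deviations of the (D, H) jitter
#'   in m (default `c(0, 0)`).
#' @param fps frame rate in Hz (default 15).
#' @param seed integer seed; the trajectory is deterministic given the
#'   seed.
#' @return an object of class `trajectory`: a data.frame with columns `t`,
#'   `D`, `H`, `lateral` (all SI units) and attributes `speed` and `fps`.
#' @examples
#' tr <- generate_trajectory(100, 30, 15, 2, jitter_sd = c(1, 0.5), seed = 1)
#' nrow(tr) # floor(duration * fps) + 1
#' @export
generate_trajectory <- function(mean_D, mean_H, speed, duration,
                                jitter_sd = c(0, 0), fps = 15, seed = 1) {
  if (mean_D <= 0 || mean_H < 0 || speed <= 0 || duration <= 0 || fps <= 0) {
    stop("trajectory arguments must be positive")
  }
  if (any(jitter_sd < 0)) stop("jitter_sd must be non-negative")
  n <- floor(duration * fps) + 1
  t <- (seq_len(n) - 1) / fps
  samples <- withr::with_seed(seed, {
    data.frame(
      t = t,
      D = mean_D + smooth_jitter(n, jitter_sd[1], fps),
      H = mean_H + smooth_jitter(n, jitter_sd[2], fps),
      lateral = speed * (t - duration / 2))
  })
  if (any(samples$D <= 0)) stop("jitter drove the distance non-positive")
  structure(samples, speed = speed, fps = fps, class = c("trajectory",
                                                         "data.frame"))
}

#' Validation scenario presets
#'
#' The nine validation scenarios: three flights per target size at
#' near-constant distance/altitude, with the reference mean distances,
#' altitudes, their standard deviations, the target dimensions
#' (small quadrocopter 0.24 m x 0.10 m, medium fixed-wing 1.20 m x 0.53 m,
#' large fixed-wing 1.99 m x 1.04 m) and the average speeds
#' (4.0 / 20.0 / 15.0 m/s for small / medium / large).
#'
#' @return a named list of nine presets (`I_S` ... `IX_L`), each a list with
#'   `name`, `target` (a [target_spec()]), `mean_D`, `mean_H`, `sd_D`,
#'   `sd_H` (m) and `speed` (m/s).
#' @examples
#' scenario_presets()$I_S$mean_D # 46.4
#' @export
scenario_presets <- function() {
  targets <- list(
    S = target_spec(0.24, 0.10, "small"),
    M = target_spec(1.20, 0.53, "medium"),
    L = target_spec(1.99, 1.04, "large"))
  speeds <- c(S = 4.0, M = 20.0, L = 15.0)
  tab <- data.frame(
    name   = c("I_S", "II_S", "III_S", "IV_M", "V_M", "VI_M",
               "VII_L", "VIII_L", "IX_L"),
    size   = c("S", "S", "S", "M", "M", "M", "L", "L", "L"),
    mean_D = c(46.4, 66.6, 96.3, 104.2, 133.6, 202.8, 129.3, 202.9, 311.5),
    sd_D   = c(0.3, 2.2, 10.8, 12.5, 13.7, 1.6, 2.5, 4.9, 2.9),
    mean_H = c(26.7, 32.0, 26.7, 36.1, 38.5, 48.8, 53.0, 96.9, 102.9),
    sd_H   = c(0.2, 0.2, 0.1, 0.5, 2.3, 1.7, 0.7, 0.7, 0.7))
  presets <- lapply(seq_len(nrow(tab)), function(i) {
    s <- tab$size[i]
    list(name = tab$name[i], target = targets[[s]],
         mean_D = tab$mean_D[i], mean_H = tab$mean_H[i],
         sd_D = tab$sd_D[i], sd_H = tab$sd_H[i], speed = unname(speeds[s]))
  })
  names(presets) <- tab$name
  presets
}

# metric size (m) of one pixel at distance D, the Eq-12 scale factor
metres_per_pixel <- function(D, intr) D * intr$sia / (intr$f * intr$y0)

# Project one trajectory sample into both cameras; returns the quantized
# pixel geometry and the rasterization parameters for the renderer.
project_sample <- function(D, H, lateral_x, target, rig, intr) {
  L <- lateral_from_altitude(D, H, rig)
  fp <- forward_project(D, L, rig, intr)
  y1q <- quantize_pixels(fp$y1)
  y2q <- quantize_pixels(fp$y2)
  mpp <- metres_per_pixel(D, intr)
  pW <- round_half_away(target$wingspan / mpp)
  pH <- round_half_away(target$height / mpp)
  col <- round_half_away(intr$x0 / 2 + lateral_x / mpp)
  r1 <- intr$y0 / 2 - y1q
  r2 <- intr$y0 / 2 - y2q
  in_frame <- fp$in_fov &&
    r1 - (pH %/% 2) >= 1 && r1 + pH %/% 2 <= intr$y0 &&
    r2 - (pH %/% 2) >= 1 && r2 + pH %/% 2 <= intr$y0 &&
    col - (pW %/% 2) >= 1 && col + pW %/% 2 <= intr$x0 &&
    pW >= 1 && pH >= 1
  list(y1 = fp$y1, y2 = fp$y2, y1q = y1q, y2q = y2q, r1 = r1, r2 = r2,
       col = col, pW = pW, pH = pH, in_fov = in_frame)
}

# Draw a filled isosceles triangle (base down) whose bounding box is
# centered at (row_center, col_center) with width pW and height pH.
render_triangle <- function(mat, row_center, col_center, pW, pH,
                            intensity = 255) {
  r_top <- row_center - floor((pH - 1) / 2)
  for (i in seq_len(pH)) {
    w <- max(1, round_half_away(pW * i / pH))
    left <- col_center - floor((w - 1) / 2)
    right <- left + w - 1
    r <- r_top + i - 1
    if (r >= 1 && r <= nrow(mat)) {
      cols <- max(1, left):min(ncol(mat), right)
      mat[r, cols] <- intensity
    }
  }
  mat
}

render_frame_matrix <- function(proj, intr, noise_sd = 0, camera = c("r1", "r2")) {
  camera <- match.arg(camera)
  m <- matrix(0, intr$y0, intr$x0)
  if (isTRUE(proj$in_fov)) {
    m <- render_triangle(m, proj[[camera]], proj$col, proj$pW, proj$pH)
  }
  if (noise_sd > 0) {
    m <- m + stats::rnorm(length(m), 0, noise_sd)
    m <- round_half_away(pmin(pmax(m, 0), 255))
  }
  m
}

#' Render a trajectory into both cameras
#'
#' Draws the target at each trajectory sample as a filled isosceles
#' triangle (base = wingspan, height = body height) of pixel width
#' `wingspan * f * y0 / (D * SIA)` -- the inverse of the metric size
#' mapping -- with its bounding box centered on the forward-projected,
#' quantized pixel position. Out-of-view samples render empty frames.
#' Gaussian background noise is added with the given seed; with zero noise
#' the frames are bit-exact functions of the trajectory.
#'
#' Frames are dense `y0 x x0` matrices; for long sequences at full
#' resolution prefer the streaming pipeline in [run_scenario()] or the
#' disk writer [simulate_to_dir()].
#'
#' @param traj a [generate_trajectory()] object.
#' @param target a [target_spec()].
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @param background_noise_sd Gaussian noise sd in intensity units
#'   (default 0).
#' @param seed integer seed for the background noise.
#' @return a list with `c1`, `c2` (lists of [new_frame()] objects) and
#'   `truth`, a data.frame per sample with the real and quantized
#'   projections (`y1`, `y2`, `y1q`, `y2q`), rendered pixel size (`pW`,
#'   `pH`), image column `col` and the `in_fov` flag.
#' @export
render_stereo_frames <- function(traj, target, rig, intr,
                                 background_noise_sd = 0, seed = 1) {
  if (any(!is.finite(traj$D)) || any(!is.finite(traj$H)) ||
      any(!is.finite(traj$lateral))) {
    stop("non-finite trajectory sample")
  }
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(traj)), function(i) {
      proj <- project_sample(traj$D[i], traj$H[i], traj$lateral[i],
                             target, rig, intr)
      list(
        f1 = new_frame(render_frame_matrix(proj, intr, background_noise_sd,
                                           "r1"), traj$t[i], "C1"),
        f2 = new_frame(render_frame_matrix(proj, intr, background_noise_sd,
                                           "r2"), traj$t[i], "C2"),
        truth = data.frame(t = traj$t[i], D = traj$D[i], H = traj$H[i],
                           y1 = proj$y1, y2 = proj$y2,
                           y1q = proj$y1q, y2q = proj$y2q,
                           pW = proj$pW, pH = proj$pH, col = proj$col,
                           in_fov = proj$in_fov))
    })
    list(c1 = lapply(out, `[[`, "f1"),
         c2 = lapply(out, `[[`, "f2"),
         truth = do.call(rbind, lapply(out, `[[`, "truth")))
  })
}

#' Simulate a scenario to disk
#'
#' Streams the rendered stereo frames of a trajectory to
#' `cam1/frame_%06d.png` and `cam2/frame_%06d.png` under `out_dir`, along
#' with `truth.csv` (per-sample ground truth), `gps.csv` (the GPS-like
#' reference track) and `manifest.json` (run metadata including the seed).
#'
#' @inheritParams render_stereo_frames
#' @param out_dir output directory (created if needed).
#' @param gps_noise_sd numeric pair: sd of the GPS-like noise on (D, H) in
#'   m (default `c(1.0, 0.5)`).
#' @return the manifest list, invisibly.
#' @export
simulate_to_dir <- function(traj, target, rig, intr, out_dir,
                            background_noise_sd = 0, seed = 1,
                            gps_noise_sd = c(1.0, 0.5)) {
  dir.create(file.path(out_dir, "cam1"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cam2"), recursive = TRUE, showWarnings = FALSE)
  truth <- withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(traj)), function(i) {
      proj <- project_sample(traj$D[i], traj$H[i], traj$lateral[i],
                             target, rig, intr)
      m1 <- render_frame_matrix(proj, intr, background_noise_sd, "r1")
      m2 <- render_frame_matrix(proj, intr, background_noise_sd, "r2")
      png::writePNG(m1 / 255,
                    file.path(out_dir, "cam1", sprintf("frame_%06d.png", i)))
      png::writePNG(m2 / 255,
                    file.path(out_dir, "cam2", sprintf("frame_%06d.png", i)))
      data.frame(frame = i, t = traj$t[i], D = traj$D[i], H = traj$H[i],
                 y1q = proj$y1q, y2q = proj$y2q, pW = proj$pW, pH = proj$pH,
                 in_fov = proj$in_fov)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  gps <- gps_like_reference(traj, noise_sd = gps_noise_sd, seed = seed + 1)
  utils::write.csv(as.data.frame(gps), file.path(out_dir, "gps.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_frames = nrow(traj), fps = attr(traj, "fps"),
    target = unclass(target), seed = seed,
    background_noise_sd = background_noise_sd,
    gps_noise_sd = gps_noise_sd,
    rig = unclass(rig), intrinsics = unclass(intr))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' GPS-like reference track
#'
#' Emulates an on-board GPS recorder: adds i.i.d. Gaussian noise to the
#' true distance and altitude at the trajectory's own timestamps.
#'
#' @param traj a [generate_trajectory()] object.
#' @param noise_sd numeric pair: noise sd on (D, H) in m (default
#'   `c(1.0, 0.5)`; the reference recorder's error magnitude is a free
#'   parameter of the simulation).
#' @param seed integer seed.
#' @return an object of class `reference_track`: a data.frame with columns
#'   `t`, `D`, `H` and attributes `noise_sd` and `seed`.
#' @export
gps_like_reference <- function(traj, noise_sd = c(1.0, 0.5), seed = 1) {
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  n <- nrow(traj)
  ref <- withr::with_seed(seed, data.frame(
    t = traj$t,
    D = traj$D + stats::rnorm(n, 0, noise_sd[1]),
    H = traj$H + stats::rnorm(n, 0, noise_sd[2])))
  structure(ref, noise_sd = noise_sd, seed = seed,
            class = c("reference_track", "data.frame"))
}
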