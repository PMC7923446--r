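#' Run a full synthetic scenario end to end
#'
#' Renders a validation scenario into both cameras frame by frame and runs
#' the complete measurement chain on the stream: two-frame motion detection
#' in each camera, stereo pairing, triangulation of distance and altitude,
#' metric size estimation and classification, and the localization /
#' classification statistics against the reference track. Frames are never
#' materialized as a sequence, so full-resolution scenarios run in constant
#' memory.
#'
#' The default flight duration is the time the orbit chord needs to cross
#' the horizontal field of view (plus a 1 m margin on each side), capped at
#' `max_duration`. Detection uses `min_area = 2` rather than
#' [detect_moving()]'s standalone default 16 because a small (0.24 m)
#' target subtends only ~3 px beyond 90 m.
#'
#' @param preset a scenario preset from [scenario_presets()], or its name
#'   (e.g. `"I_S"`).
#' @param rig a [rig_geometry()].
#' @param intr a [camera_intrinsics()].
#' @param fps frame rate in Hz (default 15).
#' @param duration flight duration in s (default: FoV crossing time, capped).
#' @param max_duration cap on the default duration in s (default 60).
#' @param seed integer seed controlling trajectory jitter, GPS-like noise
#'   and background noise.
#' @param background_noise_sd Gaussian background noise sd (default 0).
#' @param threshold,min_area,max_x_offset detection and pairing parameters
#'   (see [detect_moving()] and [pair_stereo()]).
#' @param reference `"truth"` compares against the noise-free trajectory,
#'   `"gps"` against a [gps_like_reference()] track.
#' @param gps_noise_sd GPS-like noise sd pair in m, used when
#'   `reference = "gps"`.
#' @return an object of class `scenario_run`: a list with `observations`
#'   (paired pixel observations, one row per detection, with appended
#'   columns `D`, `H`, `dD`, `PW_m`, `PH_m`, `Oapprox_m2`, `size_class`),
#'   `stats` (from [localization_stats()]), `majority_class`,
#'   `class_counts`, `mean_Oapprox`, `class_of_mean`, `n_frames`,
#'   `n_in_fov`, `efficiency` (percent of in-view frame pairs that yielded
#'   a detection), `trajectory`, `reference`, and the run parameters.
#' @examples
#' \donttest{
#' run <- run_scenario("I_S", duration = 4, seed = 1)
#' run$stats$dD_rel
#' }
#' @export
run_scenario <- function(preset, rig = rig_geometry(),
                         intr = camera_intrinsics(), fps = 15,
                         duration = NULL, max_duration = 60, seed = 1,
                         background_noise_sd = 0, threshold = 20,
                         min_area = 2, max_x_offset = 10,
                         reference = c("truth", "gps"),
                         gps_noise_sd = c(1.0, 0.5)) {
  reference <- match.arg(reference)
  if (is.character(preset)) preset <- scenario_presets()[[preset]]
  if (is.null(preset)) stop("unknown scenario preset")
  target <- preset$target
  if (is.null(duration)) {
    x_max <- (intr$x0 / 2) * metres_per_pixel(preset$mean_D, intr)
    duration <- min(max_duration, 2 * (x_max + 1) / preset$speed)
  }
  traj <- generate_trajectory(preset$mean_D, preset$mean_H, preset$speed,
                              duration, jitter_sd = c(preset$sd_D, preset$sd_H),
                              fps = fps, seed = seed)
  n <- nrow(traj)
  obs_list <- vector("list", n)
  n_in_fov <- 0L
  withr::with_seed(seed + 2L, {
    prev <- NULL
    for (i in seq_len(n)) {
      proj <- project_sample(traj$D[i], traj$H[i], traj$lateral[i],
                             target, rig, intr)
      m1 <- render_frame_matrix(proj, intr, background_noise_sd, "r1")
      m2 <- render_frame_matrix(proj, intr, background_noise_sd, "r2")
      if (!is.null(prev)) {
        if (isTRUE(proj$in_fov)) n_in_fov <- n_in_fov + 1L
        b1 <- detect_moving(prev$m1, m1, threshold = threshold,
                            min_area = min_area, mask_current = TRUE)
        b2 <- detect_moving(prev$m2, m2, threshold = threshold,
                            min_area = min_area, mask_current = TRUE)
        obs_list[[i]] <- pair_stereo(b1, b2, intr,
                                     max_x_offset = max_x_offset,
                                     t = traj$t[i])
      }
      prev <- list(m1 = m1, m2 = m2)
    }
  })
  obs <- do.call(rbind, obs_list[!vapply(obs_list, is.null, logical(1))])
  if (is.null(obs)) obs <- empty_observations()
  ref <- if (reference == "gps") {
    gps_like_reference(traj, noise_sd = gps_noise_sd, seed = seed + 1L)
  } else {
    structure(data.frame(t = traj$t, D = traj$D, H = traj$H),
              class = c("reference_track", "data.frame"))
  }
  out <- list(preset = preset$name, target = target, trajectory = traj,
              reference = ref, observations = obs,
              n_frames = n, n_in_fov = n_in_fov,
              params = list(fps = fps, duration = duration, seed = seed,
                            background_noise_sd = background_noise_sd,
                            threshold = threshold, min_area = min_area))
  if (nrow(obs) > 0) {
    loc <- triangulate_distance(obs, rig, intr)
    size <- size_from_pixels(obs$pW, obs$pH, loc$D, intr)
    obs$D <- loc$D; obs$H <- loc$H; obs$dD <- loc$dD
    obs$PW_m <- size$PW; obs$PH_m <- size$PH; obs$Oapprox_m2 <- size$Oapprox
    obs$size_class <- classify_size(size$Oapprox)
    out$observations <- obs
    out$stats <- localization_stats(loc, ref)
    out$class_counts <- table(obs$size_class)
    out$majority_class <- names(which.max(out$class_counts))
    out$mean_Oapprox <- mean(size$Oapprox)
    out$class_of_mean <- as.character(classify_size(out$mean_Oapprox))
    out$efficiency <- round_half_away(100 * nrow(obs) / max(n_in_fov, 1))
  }
  class(out) <- "scenario_run"
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("scenario_run %s: %d frames, %d in view, %d detections\n",
              x$preset, x$n_frames, x$n_in_fov, nrow(x$observations)))
  if (!is.null(x$stats)) {
    cat(sprintf("  distance: sys %.1f m vs ref %.1f m (rel err %.1f%%)\n",
                x$stats$mean_D_sys, x$stats$mean_D_ref, x$stats$dD_rel))
    cat(sprintf("  altitude: sys %.1f m vs ref %.1f m (rel err %.1f%%)\n",
                x$stats$mean_H_sys, x$stats$mean_H_ref, x$stats$dH_rel))
    cat(sprintf("  majority class: %s (true %s), mean Oapprox %.3f m^2\n",
                x$majority_class, x$target$label, x$mean_Oapprox))
  }
  invisible(x)
}
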