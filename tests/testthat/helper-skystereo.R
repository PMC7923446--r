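# Reference configuration of the prototype rig.
ref_intr <- function() camera_intrinsics(y0 = 1440, phi0 = 48.8, f = 3,
                                         sia = 3.76, x0 = 1080)
ref_rig <- function(alpha = 24.4) rig_geometry(B = 1, alpha = alpha)

# Down-scaled sensor for image-level tests (same FoV, 10x fewer pixels).
tiny_intr <- function() camera_intrinsics(y0 = 144, phi0 = 48.8, f = 3,
                                          sia = 3.76, x0 = 96)

# Random triangulable observations (signed center-origin, disparity >= 1).
random_observations <- function(n, intr, seed = 1) {
  withr::with_seed(seed, {
    half <- intr$y0 / 2
    y2 <- runif(n, -half, half - 2)
    y1 <- y2 + runif(n, 1, half - y2)
    data.frame(y1 = y1, y2 = y2)
  })
}

# Draw the same silhouette the renderer uses (base-down isosceles triangle).
draw_triangle <- function(nrow, ncol, row_center, col_center, pW, pH) {
  skystereo:::render_triangle(matrix(0, nrow, ncol), row_center, col_center,
                              pW, pH)
}
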