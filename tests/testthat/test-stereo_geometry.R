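test_that("pixel-tangent mapping matches the pinhole relation and inverts", {
  intr <- ref_intr()
  expect_identical(pixel_to_tangent(0, intr), 0)
  expect_equal(pixel_to_tangent(intr$y0 / 2, intr), tan(pi * 24.4 / 180))
  # 100 * tan(24.4 deg) / 720
  expect_equal(pixel_to_tangent(100, intr), 0.063003, tolerance = 1e-5)
  y <- c(-700, -3.2, 0, 0.5, 719)
  expect_equal(tangent_to_pixel(pixel_to_tangent(y, intr), intr), y)
  expect_error(pixel_to_tangent(721, intr), "outside the sensor")
})

test_that("quantization rounds half away from zero and clips to the sensor", {
  expect_identical(quantize_pixels(c(0.4, -0.5, 100.5, -100.5, 0)),
                   c(0, -1, 101, -101, 0))
  expect_identical(quantize_pixels(c(-900, 900), ref_intr()), c(-720, 720))
})

test_that("triangulation reproduces the closed-form distances", {
  intr <- ref_intr()
  # classical configuration, full-edge disparity
  loc0 <- triangulate_distance(data.frame(y1 = 360, y2 = -360),
                               ref_rig(alpha = 0), intr)
  expect_equal(loc0$D, 2.2045, tolerance = 1e-4)
  # rotated axes
  loc <- triangulate_distance(data.frame(y1 = 100, y2 = -100), ref_rig(), intr)
  expect_equal(loc$D, 7.020775, tolerance = 1e-6)
  expect_equal(loc$dD, loc$D / 200)
  expect_error(
    triangulate_distance(data.frame(y1 = 10, y2 = 9.5), ref_rig(), intr),
    "non-triangulable")
})

test_that("classical limit: rotated formula collapses to B*y0/(2*tan*(y1-y2))", {
  intr <- ref_intr()
  rig0 <- ref_rig(alpha = 0)
  disparity <- 1:1439
  obs <- data.frame(y1 = 719, y2 = 719 - disparity)
  expect_equal(triangulate_distance(obs, rig0, intr)$D,
               classical_distance(disparity, rig0$B, intr))
  expect_equal(classical_distance(720, 1, intr), 2.2045, tolerance = 1e-4)
  expect_equal(classical_distance(100, 2, intr),
               2 * classical_distance(100, 1, intr))
  expect_equal(classical_distance(intr$y0, 1, intr),
               1 / (2 * tan(pi * 24.4 / 180)))
  expect_error(classical_distance(0, 1, intr), "disparity")
})

test_that("angle- and pixel-route distances agree on random observations", {
  intr <- ref_intr()
  for (alpha in c(0, 10, 24.4, 45)) {
    rig <- ref_rig(alpha)
    obs <- random_observations(10000, intr, seed = 7 + alpha)
    loc <- triangulate_distance(obs, rig, intr)
    # recompute the angle route independently of the package internals
    t0 <- tan(pi * intr$phi0 / 360)
    tan1 <- obs$y1 * t0 / (intr$y0 / 2)
    tan2 <- -obs$y2 * t0 / (intr$y0 / 2)
    a <- pi * alpha / 180
    D5 <- rig$B * (cos(a) - sin(a) * tan2) / (tan1 + tan2)
    expect_lt(max(abs(D5 - loc$D) / abs(loc$D)), 1e-9)
  }
})

test_that("distance is decreasing in disparity and increasing in y2", {
  intr <- ref_intr()
  rig <- ref_rig()
  # fixed y2, growing disparity
  d <- seq(1, 600, by = 1)
  D <- triangulate_distance(data.frame(y1 = -100 + d, y2 = -100), rig, intr)$D
  expect_true(all(diff(D) < 0))
  # fixed disparity, growing y2 (alpha > 0 only)
  y2 <- seq(-700, 680, by = 10)
  D2 <- triangulate_distance(data.frame(y1 = y2 + 30, y2 = y2), rig, intr)$D
  expect_true(all(diff(D2) > 0))
  D2c <- triangulate_distance(data.frame(y1 = y2 + 30, y2 = y2),
                              ref_rig(alpha = 0), intr)$D
  expect_equal(diff(D2c), rep(0, length(y2) - 1))
})

test_that("forward projection round-trips through triangulation exactly", {
  intr <- ref_intr()
  for (alpha in c(0, 24.4, 40)) {
    rig <- ref_rig(alpha)
    cases <- withr::with_seed(11, data.frame(D = runif(500, 2, 400),
                                             lateral = runif(500, -80, 80)))
    fp <- forward_project(cases$D, cases$lateral, rig, intr)
    ok <- fp$in_fov & (fp$y1 - fp$y2) >= 1
    loc <- triangulate_distance(fp[ok, ], rig, intr)
    expect_equal(loc$D, cases$D[ok], tolerance = 1e-12)
  }
  # on-axis object projects to the C1 image center
  expect_equal(forward_project(10, 0, ref_rig(), intr)$y1, 0)
  # inverse of the worked triangulation example: y1 = 100 maps back to y2 = -100
  D <- 7.0207747
  lateral <- D * pixel_to_tangent(100, intr)
  fp <- forward_project(D, lateral, ref_rig(), intr)
  expect_equal(fp$y2, -100, tolerance = 1e-5)
  expect_true(fp$in_fov)
  expect_false(forward_project(1, 30, ref_rig(), intr)$in_fov)
})

test_that("triangulation intermediates satisfy the geometric identities", {
  intr <- ref_intr()
  rig <- ref_rig()
  a <- pi * rig$alpha / 180
  cases <- withr::with_seed(3, data.frame(D = runif(200, 2, 300),
                                          lateral = runif(200, -50, 50)))
  fp <- forward_project(cases$D, cases$lateral, rig, intr)
  expect_equal(fp$b1 + fp$b2, rep(rig$B * cos(a), 200))
  expect_equal(fp$d1 + fp$d2, rep(rig$B * sin(a), 200))
  expect_equal(fp$Dk, cases$D)
  expect_equal(fp$Db - fp$d1, cases$D)
})

test_that("altitude: literal cotangent formula behaves as stated", {
  intr <- ref_intr()
  phi_half <- intr$phi0 / 2
  expect_equal(altitude_eq10(37.5, 45 - phi_half, intr), 37.5)
  expect_equal(altitude_eq10(80, 90 - phi_half, intr), 0, tolerance = 1e-12)
  expect_equal(altitude_eq10(100, 10, intr), 146.1, tolerance = 1e-3)
  expect_error(altitude_eq10(100, 180 - phi_half, intr), "degenerate")
})

test_that("altitude from the ray inverts the forward model", {
  intr <- ref_intr()
  rig <- rig_geometry(B = 1, alpha = 24.4, mount_height = 2)
  # object on the C1 optical axis at alpha = 0 sits at mount height
  rig0 <- rig_geometry(B = 1, alpha = 0, mount_height = 3.5)
  fp0 <- forward_project(60, 0, rig0, intr)
  loc0 <- triangulate_distance(fp0, rig0, intr)
  expect_equal(loc0$H, 3.5)
  # sub-pixel round trip at (D, H) = (150, 40)
  lateral <- lateral_from_altitude(150, 40, rig)
  fp <- forward_project(150, lateral, rig, intr)
  loc <- triangulate_distance(fp, rig, intr)
  expect_equal(loc$D, 150)
  expect_equal(loc$H, 40)
  # under 1-px quantization the altitude error stays within the bound
  # obtained by brute force over +/- 0.5 px perturbations of both pixels
  for (case in list(c(50, 20), c(150, 40), c(280, 90))) {
    lat <- lateral_from_altitude(case[1], case[2], rig)
    fp <- forward_project(case[1], lat, rig, intr)
    e <- seq(-0.5, 0.5, by = 0.05)
    pert <- expand.grid(e1 = e, e2 = e)
    pobs <- data.frame(y1 = fp$y1 + pert$e1, y2 = fp$y2 + pert$e2)
    bound <- max(abs(triangulate_distance(pobs, rig, intr)$H - case[2]))
    q <- data.frame(y1 = quantize_pixels(fp$y1), y2 = quantize_pixels(fp$y2))
    locq <- triangulate_distance(q, rig, intr)
    expect_lte(abs(locq$H - case[2]), bound + 0.01)
  }
})
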