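test_that("trajectories sample the requested flight", {
  tr <- generate_trajectory(100, 30, 15, 2, fps = 15, seed = 1)
  expect_identical(nrow(tr), 31L)            # floor(duration*fps) + 1
  expect_equal(unique(tr$D), 100)            # zero jitter -> constant
  expect_equal(unique(tr$H), 30)
  expect_equal(diff(tr$t), rep(1 / 15, 30))
  # lateral chord crosses the center at mid-flight at the given speed
  expect_equal(tr$lateral[1], -15)
  expect_equal(diff(tr$lateral), rep(1, 30))
})

test_that("trajectory jitter has the requested spread and is reproducible", {
  tr <- generate_trajectory(200, 50, 10, 666, jitter_sd = c(3, 1.2),
                            fps = 15, seed = 42)
  expect_gt(nrow(tr), 9900)
  expect_equal(sd(tr$D), 3, tolerance = 1e-9)
  expect_equal(sd(tr$H), 1.2, tolerance = 1e-9)
  tr2 <- generate_trajectory(200, 50, 10, 666, jitter_sd = c(3, 1.2),
                             fps = 15, seed = 42)
  expect_identical(tr$D, tr2$D)
  tr3 <- generate_trajectory(200, 50, 10, 666, jitter_sd = c(3, 1.2),
                             fps = 15, seed = 43)
  expect_false(identical(tr$D, tr3$D))
})

test_that("scenario presets encode the nine validation flights", {
  p <- scenario_presets()
  expect_length(p, 9)
  labels <- vapply(p, function(x) x$target$label, character(1))
  expect_identical(as.integer(table(labels)[c("small", "medium", "large")]),
                   rep(3L, 3))
  expect_equal(p$I_S$mean_D, 46.4)
  expect_equal(p$I_S$mean_H, 26.7)
  expect_identical(p$I_S$target$label, "small")
  expect_equal(p$IX_L$mean_D, 311.5)
  expect_equal(p$IX_L$mean_H, 102.9)
  expect_equal(p$I_S$speed, 4.0)
  expect_equal(p$IV_M$speed, 20.0)
  expect_equal(p$IX_L$speed, 15.0)
})

test_that("rendering scales the target by the inverse size mapping", {
  intr <- ref_intr()
  rig <- ref_rig()
  tr <- generate_trajectory(100, 30, 5, 0.2, fps = 15, seed = 1)
  out <- render_stereo_frames(tr, target_spec(1.2, 0.5, "medium"), rig, intr)
  expect_identical(unique(out$truth$pW), 14)   # round(1.2*3*1440/(100*3.76))
  # zero noise: measured bbox equals the rendered width exactly
  px <- out$c1[[1]]$pixels
  on <- which(px > 0, arr.ind = TRUE)
  expect_identical(diff(range(on[, 2])) + 1L, 14L)
  expect_equal(diff(range(on[, 1])) + 1L, unique(out$truth$pH))
  # rendered pixel size never grows with distance
  sizes <- vapply(seq(40, 300, by = 20), function(D) {
    tr <- generate_trajectory(D, 30, 5, 0.1, fps = 15, seed = 1)
    render_stereo_frames(tr, target_spec(1.2, 0.5, "medium"), rig,
                         intr)$truth$pW[1]
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(render_stereo_frames(
    data.frame(t = 0, D = NaN, H = 1, lateral = 0),
    target_spec(1.2, 0.5, "medium"), rig, intr), "non-finite")
})

test_that("GPS-like reference adds unbiased noise on the same timestamps", {
  tr <- generate_trajectory(150, 40, 10, 666, fps = 15, seed = 2)
  same <- gps_like_reference(tr, noise_sd = c(0, 0), seed = 9)
  expect_equal(same$D, tr$D)
  expect_equal(same$H, tr$H)
  ref <- gps_like_reference(tr, noise_sd = c(1, 0.5), seed = 9)
  expect_identical(ref$t, tr$t)
  n <- nrow(tr)
  expect_lt(abs(mean(ref$D - tr$D)), 3 / sqrt(n))       # 3 SE, sd = 1
  expect_lt(abs(mean(ref$H - tr$H)), 3 * 0.5 / sqrt(n))
  ref2 <- gps_like_reference(tr, noise_sd = c(1, 0.5), seed = 10)
  expect_identical(ref2$t, ref$t)
  expect_false(identical(ref2$D, ref$D))
})

test_that("noiseless pipeline observations equal the quantized projections", {
  # micro-rig: same FoV at a tenth of the resolution, target climbing so
  # consecutive silhouettes never touch (old/new positions stay disjoint)
  intr <- tiny_intr()
  rig <- ref_rig()
  n <- 10
  traj <- structure(
    data.frame(t = (0:(n - 1)) / 15, D = rep(8, n),
               H = seq(2, 5, length.out = n), lateral = rep(0, n)),
    speed = 1, fps = 15, class = c("trajectory", "data.frame"))
  tgt <- target_spec(0.35, 0.21, "small")   # 5 x 3 px at 8 m (odd height)
  out <- render_stereo_frames(traj, tgt, rig, intr)
  expect_true(all(out$truth$in_fov))
  for (i in 2:n) {
    b1 <- detect_moving(out$c1[[i - 1]], out$c1[[i]], min_area = 2,
                        mask_current = TRUE)
    b2 <- detect_moving(out$c2[[i - 1]], out$c2[[i]], min_area = 2,
                        mask_current = TRUE)
    obs <- pair_stereo(b1, b2, intr, t = traj$t[i])
    expect_identical(nrow(obs), 1L)
    expect_equal(obs$y1, out$truth$y1q[i])
    expect_equal(obs$y2, out$truth$y2q[i])
    # triangulated distance recovers the truth within the quantization bound
    loc <- triangulate_distance(obs, rig, intr)
    expect_lte(abs(loc$D - traj$D[i]), loc$dD)
  }
})

test_that("simulated scenes round-trip through disk", {
  intr <- tiny_intr()
  rig <- ref_rig()
  n <- 6
  traj <- structure(
    data.frame(t = (0:(n - 1)) / 15, D = rep(8, n),
               H = seq(2, 4, length.out = n), lateral = rep(0, n)),
    speed = 1, fps = 15, class = c("trajectory", "data.frame"))
  dir <- withr::local_tempdir()
  simulate_to_dir(traj, target_spec(0.35, 0.21, "small"), rig, intr, dir,
                  seed = 4)
  expect_true(file.exists(file.path(dir, "cam1", "frame_000001.png")))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), n)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$seed, 4L)
  obs <- detect_sequence(dir, intr, min_area = 2, mask_current = TRUE,
                         times_csv = file.path(dir, "truth.csv"))
  expect_equal(nrow(obs), n - 1)
  expect_equal(obs$y1, truth$y1q[-1])
  expect_equal(obs$y2, truth$y2q[-1])
})
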