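test_that("grip aperture is the per-sample 3-D marker distance", {
  df <- data.frame(t_s = seq(0, 0.11, by = 0.01),
                   thumb_x_cm = 0, thumb_y_cm = 0, thumb_z_cm = 0,
                   finger_x_cm = 3, finger_y_cm = 4, finger_z_cm = 0)
  tr <- as_trajectory(df)
  expect_equal(grip_aperture(tr), rep(5, 12))
  df2 <- df
  df2[c("finger_x_cm", "finger_y_cm")] <- 0
  expect_equal(grip_aperture(as_trajectory(df2)), rep(0, 12))
})

test_that("trajectory validation enforces schema, ordering and uniformity", {
  t <- seq(0, 0.11, by = 0.01)
  ok <- raw_traj(t, x = 30 - t, y_half = 1, z = 0)
  expect_s3_class(as_trajectory(ok), "trajectory")
  expect_error(as_trajectory(ok[-1, ][1:5, ]), "at least 10")
  expect_error(as_trajectory(ok[c(1:5, 5, 6:11), ]), "increasing")
  jitter <- ok
  jitter$t_s[6] <- jitter$t_s[6] + 0.004
  expect_error(as_trajectory(jitter), "uniform")
  expect_error(as_trajectory(ok[, -3]), "missing columns")
})

test_that("movement onset is found at a sustained speed threshold", {
  # 20 stationary samples, then steady 5 cm/s motion (first moving sample: 21)
  t <- seq(0, 0.59, by = 0.01)
  x <- c(rep(30, 20), 30 - 5 * (t[21:60] - t[20]))
  tr <- as_trajectory(raw_traj(t, x, y_half = 0.2, z = 0))
  onset <- detect_onset(tr, speed_threshold = 2)
  expect_lte(abs(onset - 21), 1)

  # threshold 0 on a moving trace: onset at or just after the first sample
  moving <- as_trajectory(raw_traj(t, 30 - 5 * t, y_half = 0.2, z = 0))
  expect_lte(detect_onset(moving, speed_threshold = 0), 2)

  # all samples stationary: a non-movement trial
  still <- as_trajectory(raw_traj(t, rep(30, 60), y_half = 0.2, z = 0))
  expect_error(detect_onset(still), "no movement onset")
})

test_that("near-target moment is the first post-peak descent below the margin", {
  z <- c(0, 3, 5, 2, 0.8, 0.2, 0.1, 0, 0, 0, 0, 0)
  t <- seq(0, 0.11, by = 0.01)
  tr <- as_trajectory(raw_traj(t, 30 - t, y_half = 1, z = z))
  expect_equal(detect_near_target(tr, height_margin = 1), 5)

  never_down <- as_trajectory(raw_traj(t, 30 - t, y_half = 1,
                                       z = c(0, 3, 5, 4.5, 4, 3.5, 3, 2.8, 2.6,
                                             2.4, 2.2, 2)))
  expect_error(detect_near_target(never_down), "never descends")

  flat <- as_trajectory(raw_traj(t, 30 - t, y_half = 1, z = rep(0.1, 12)))
  expect_error(detect_near_target(flat), "never rises")
})

test_that("near-target index is monotone in the height margin", {
  tr <- synth_trajectory(6.5, 4.0, generator_config())
  idx <- vapply(c(0.5, 1, 1.5, 2), function(m) detect_near_target(tr, m),
                numeric(1))
  expect_true(all(diff(idx) <= 0))  # larger margin never later
})

test_that("MGA extraction takes the window maximum with earliest-tie breaking", {
  t <- seq(0, 0.11, by = 0.01)
  ap <- c(0.4, 0.4, 0.4, 3.0, 6.2, 5.8, 5, 4, 4, 4, 4, 4)
  tr <- as_trajectory(raw_traj(t, 30 - t, y_half = ap / 2, z = 0))
  res <- extract_mga(tr, list(onset_index = 2, near_target_index = 8))
  expect_equal(res$mga_cm, 6.2)
  expect_equal(res$mga_index, 5)

  flat <- as_trajectory(raw_traj(t, 30 - t, y_half = 2, z = 0))
  res_flat <- extract_mga(flat, list(onset_index = 3, near_target_index = 10))
  expect_equal(res_flat$mga_cm, 4)
  expect_equal(res_flat$mga_index, 3)

  expect_error(extract_mga(tr, list(onset_index = 9, near_target_index = 4)),
               "window")
})

test_that("synthetic trajectories honour the stated geometry", {
  cfg <- generator_config()
  tr <- synth_trajectory(6.5, 4.0, cfg)
  expect_equal(nrow(tr), 121)  # 0.6 s at 200 Hz, endpoints included
  ap <- grip_aperture(tr)
  expect_equal(ap[1], 0.4)                     # starting aperture
  expect_equal(ap[length(ap)], 4.0)            # closes to contact separation
  expect_equal(tr$thumb_x_cm[1], 30)           # start 30 cm lateral
  expect_lt(abs(tr$thumb_x_cm[121]), 1e-9)     # ends at the target
  ev <- grasp_events(tr)
  expect_equal(ev$mga_cm, 6.5)
  expect_lt(ev$mga_index, ev$near_target_index)
  expect_gt(ev$mga_index, ev$onset_index)
  expect_error(synth_trajectory(3, 4, cfg), "contact separation")
  expect_error(synth_trajectory(0.3, 0.2, cfg), "starting aperture")
})

test_that("event chain recovers the embedded MGA on noise-free trajectories", {
  cfg <- generator_config()
  set.seed(33)
  for (i in 1:25) {
    target <- runif(1, 4.5, 8.5)
    tr <- synth_trajectory(target, runif(1, 1.5, 4), cfg)
    expect_equal(grasp_events(tr)$mga_cm, target, tolerance = 1e-12)
  }
})

test_that("MGA is invariant under rigid motion of the whole trajectory", {
  tr <- synth_trajectory(7.2, 3.0, generator_config())
  set.seed(8)
  theta <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(theta[1]), -sin(theta[1])),
              c(0, sin(theta[1]), cos(theta[1])))
  Rz <- rbind(c(cos(theta[3]), -sin(theta[3]), 0),
              c(sin(theta[3]), cos(theta[3]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  shift <- runif(3, -10, 10)
  thumb <- t(R %*% t(as.matrix(tr[c("thumb_x_cm", "thumb_y_cm", "thumb_z_cm")]))) +
    matrix(shift, nrow(tr), 3, byrow = TRUE)
  finger <- t(R %*% t(as.matrix(tr[c("finger_x_cm", "finger_y_cm", "finger_z_cm")]))) +
    matrix(shift, nrow(tr), 3, byrow = TRUE)
  moved <- tr
  moved[c("thumb_x_cm", "thumb_y_cm", "thumb_z_cm")] <- thumb
  moved[c("finger_x_cm", "finger_y_cm", "finger_z_cm")] <- finger
  expect_equal(max(grip_aperture(moved)), max(grip_aperture(tr)),
               tolerance = 1e-9)
})

test_that("aperture at a transport distance picks the first qualifying sample", {
  # linear transport 0 -> 30 cm over 120 steps (121 samples)
  t <- seq(0, 0.6, length.out = 121)
  x <- 30 * t / 0.6
  ap <- seq(0.4, 6, length.out = 121)
  tr <- as_trajectory(raw_traj(t, x, y_half = ap / 2, z = 0))
  res <- aperture_at_distance(tr, 20)
  expect_lte(abs(res$index - 81), 1)
  expect_equal(res$aperture_cm, ap[res$index])
  expect_equal(aperture_at_distance(tr, 0)$index, 1)
  expect_error(aperture_at_distance(tr, 31), "never reaches")
})
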