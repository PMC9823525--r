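neutral_calibration <- function(model, beta = NULL, n_frames = 10) {
  p <- forward_kinematics(model, scales = beta,
                          theta = neutral_pose(model))$marker_positions
  pos <- array(NA_real_, c(n_frames, ncol(p), 3))
  for (f in seq_len(n_frames)) pos[f, , ] <- t(p)
  marker_trajectory(colnames(p), (seq_len(n_frames) - 1) / 30, pos)
}

test_that("marker-pair scaling is self-consistent at the default model", {
  model <- default_model_cached()
  sc <- scale_from_markers(model, neutral_calibration(model))
  expect_equal(max(abs(sc - 1)), 0, tolerance = 1e-9)
})

test_that("marker-pair scaling recovers subject scales from clean markers", {
  model <- default_model_cached()
  sc <- scale_from_markers(model, neutral_calibration(model, beta = 1.1))
  expect_equal(max(abs(sc - 1.1)), 0, tolerance = 1e-6)
  set.seed(30)
  beta <- matrix(runif(3 * 17, 0.9, 1.15), 3,
                 dimnames = list(NULL, colnames(default_body_scales(model))))
  sc <- scale_from_markers(model, neutral_calibration(model, beta = beta))
  expect_equal(max(abs(sc - beta)), 0, tolerance = 1e-6)
})

test_that("scaling error under jitter follows the noise propagation", {
  model <- default_model_cached()
  calib <- corrupt_markers(
    neutral_calibration(model, beta = 1.1, n_frames = 10),
    noise_spec(gaussian_sigma = 0.005, bias_norm_range = c(0, 0),
               occlusion_rate = 0, seed = 31))
  sc <- scale_from_markers(model, calib)
  # each pair distance has sd sigma*sqrt(2) per frame; the mean over 10
  # frames propagates to a relative scale sd of sigma*sqrt(2/10)/d0
  cm <- compiled_default()
  long <- body_long_axes(model)
  for (b in names(long)) {
    d0 <- 1.1 * cm$reference_lengths[[b]] / 1000
    tol <- 4 * 0.005 * sqrt(2 / 10) / d0 + 2 * 0.005^2 / d0^2
    expect_lt(abs(sc[long[[b]], b] - 1.1) / 1.1, tol)
  }
  # long reference segments recover within about one percent
  expect_lt(abs(sc[2, "l_femur"] - 1.1) / 1.1, 0.01)
})

test_that("scaling fails informatively on unusable calibration data", {
  model <- default_model_cached()
  calib <- neutral_calibration(model)
  calib$missing[, 1] <- TRUE   # pelvis_o never observed
  calib$positions[, 1, ] <- NA_real_
  expect_error(scale_from_markers(model, calib), "never simultaneously")
  cfg <- default_scale_pairs(model)
  cfg$marker_b[1] <- cfg$marker_a[1]
  expect_error(scale_from_markers(model, neutral_calibration(model), cfg),
               "zero default-model distance")
})

test_that("single-frame IK is a fixed point at the true configuration", {
  model <- default_model_cached()
  cfgr <- random_configuration(model, 32)
  pose <- forward_kinematics(model, cfgr$beta, cfgr$theta)
  res <- solve_ik_frame(model, cfgr$beta, t(pose$marker_positions),
                        theta_init = cfgr$theta)
  expect_equal(as.numeric(res$theta), as.numeric(cfgr$theta),
               tolerance = 1e-9)
  expect_lt(max(res$segment_rms, na.rm = TRUE), 1e-9)
  expect_true(res$converged)
})

test_that("single-frame IK recovers the pose from the neutral start", {
  model <- default_model_cached()
  set.seed(33)
  cm <- compiled_default()
  rg <- cm$coord_ranges
  lo <- ifelse(is.finite(rg[1, ]), pmax(rg[1, ], -0.6), -0.6)
  hi <- ifelse(is.finite(rg[2, ]), pmin(rg[2, ], 0.6), 0.6)
  theta <- setNames(runif(cm$n_coord, lo, hi), cm$coord_names)
  pose <- forward_kinematics(model, NULL, theta)
  res <- solve_ik_frame(model, NULL, t(pose$marker_positions))
  expect_lt(max(abs(res$theta - theta)) * 180 / pi, 0.1)
})

test_that("a displaced marker inflates its own segment's residual", {
  model <- default_model_cached()
  theta <- neutral_pose(model)
  pose <- forward_kinematics(model, NULL, theta)
  obs <- t(pose$marker_positions)
  ix <- which(compiled_default()$marker_names == "l_forearm_y")
  obs[ix, 1] <- obs[ix, 1] + 0.050
  res <- solve_ik_frame(model, NULL, obs, theta_init = theta)
  seg <- res$segment_rms
  expect_equal(names(which.max(seg)), "l_forearm")
})

test_that("sequence IK recovers noise-free motions with no rejections", {
  model <- default_model_cached()
  mot <- simulate_motion(model, trajectory_spec(duration = 2, seed = 34))
  traj <- fk_trajectory(model, mot)
  ik <- solve_ik_sequence(model, trajectory = traj)
  expect_lt(angle_errors(ik$motion$angles, mot$angles)$mae, 0.1)
  expect_equal(sum(!ik$motion$valid), 0L)
  # root rotation is recovered too
  f <- length(mot$timestamps)
  expect_equal(ik$motion$root_rotation[, , f], mot$root_rotation[, , f],
               tolerance = 1e-4)
})

test_that("an outlier frame is rejected and its neighbours are untouched", {
  model <- default_model_cached()
  mot <- simulate_motion(model, trajectory_spec(duration = 1, seed = 35))
  traj <- fk_trajectory(model, mot)
  bad <- 20L
  set.seed(36)
  dirs <- matrix(rnorm(3 * dim(traj$positions)[2]), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  traj$positions[bad, , ] <- traj$positions[bad, , ] + 0.100 * dirs
  ik <- solve_ik_sequence(model, trajectory = traj)
  expect_true(all(!ik$motion$valid[bad, ]))
  expect_true(all(ik$motion$valid[bad - 1, ]))
  expect_true(all(ik$motion$valid[bad + 1, ]))
  # rejections grow monotonically as the threshold tightens
  counts <- vapply(c(50, 20, 10, 5, 1), function(mm) {
    flags <- skelkin:::recount_rejections(ik$segment_rms, model, mm)
    sum(flags)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("an empty trajectory produces an empty result", {
  model <- default_model_cached()
  cm <- compiled_default()
  traj <- marker_trajectory(cm$marker_names, numeric(0),
                            array(0, c(0, cm$n_marker, 3)))
  ik <- solve_ik_sequence(model, trajectory = traj)
  expect_equal(length(ik$motion$timestamps), 0L)
  expect_equal(nrow(ik$motion$angles), 0L)
})

test_that("the low-pass filter preserves passband content and removes noise", {
  const <- rep(1.5, 100)
  expect_equal(lowpass_smooth(const, 6, 100), const, tolerance = 1e-9)
  t <- seq(0, 2, by = 0.01)
  sine <- sin(2 * pi * 1 * t)
  out <- lowpass_smooth(sine, 10, 100)
  expect_lt(max(abs(out - sine)) / max(abs(sine)), 0.01)
  set.seed(37)
  noise <- rnorm(500)
  expect_lt(var(lowpass_smooth(noise, 5, 100)), var(noise))
})
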