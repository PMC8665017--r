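test_that("stimulus protocol places pulses on the pulse+interval grid", {
  p <- gen_stimulus_protocol()
  expect_length(p$onsets, 6)
  expect_equal(p$onsets[2], 35)         # 5 s pulse + 30 s interval
  expect_equal(p$intensities, c(0.02, 0.04, 0.12, 0.28, 0.37, 0.68))
  expect_equal(p$modulation_hz, 50)
  expect_equal(p$duty, 0.5)

  one <- gen_stimulus_protocol(intensities = 0.3, pulse_duration = 5)
  expect_equal(one$total_span, 5)

  tri <- gen_stimulus_protocol(intensities = c(1, 2, 3), pulse_duration = 2,
                               inter_pulse = 3)
  expect_equal(tri$onsets, (0:2) * (2 + 3))

  expect_error(gen_stimulus_protocol(pulse_duration = 0), class = "fcmap_invalid_parameter")
  expect_error(gen_stimulus_protocol(intensities = c(0.1, -1)),
               class = "fcmap_invalid_parameter")
  expect_error(gen_stimulus_protocol(intensities = numeric(0)),
               class = "fcmap_invalid_parameter")
})

test_that("protocol drive is the duty-scaled envelope at frame resolution", {
  p <- gen_stimulus_protocol(intensities = c(1, 2), pulse_duration = 2,
                             inter_pulse = 3, duty = 0.5)
  d <- fcmap:::protocol_drive(p, c(0, 1, 2.5, 5, 6, 8))
  expect_equal(d, c(0.5, 0.5, 0, 1, 1, 0))
})

test_that("gcamp model amplitude map saturates and its kernel integrates to 1", {
  m <- gcamp_model()
  ints <- c(0.02, 0.04, 0.12, 0.28, 0.37, 0.68)
  amps <- steady_state_dff(m, ints)
  expect_true(all(diff(amps) > 0))
  expect_true(all(amps < m$amp_max))
  # kernel step response converges to 1 (unit integral)
  expect_equal(fcmap:::kernel_step(1e4, m$rise_tau, m$decay_tau), 1)
  expect_equal(fcmap:::kernel_step(-1, m$rise_tau, m$decay_tau), 0)
  expect_error(gcamp_model(rise_tau = 1, decay_tau = 1),
               class = "fcmap_invalid_parameter")
})

test_that("roi movie: null connectivity and zero noise give a constant movie", {
  scene <- scene_params(image_height = 24, image_width = 42, n_frames = 20,
                        frame_rate = 2.5, baseline_fluorescence = 100)
  sim <- gen_roi_movie(scene, demo_model(), two_roi_planted(0, 0),
                       single_pulse_protocol(), two_roi_layout())
  expect_equal(length(unique(round(sim$movie$frames[, 12, 12], 12))), 1)
  expect_true(all(sim$ground_truth$dff_true == 0))
  # every frame identical
  expect_equal(max(apply(sim$movie$frames, c(2, 3), function(v) diff(range(v)))), 0)
})

test_that("roi movie steady state matches the closed-form amplitude map", {
  scene <- scene_params(image_height = 24, image_width = 42, n_frames = 100,
                        frame_rate = 2.5, baseline_fluorescence = 100)
  m <- demo_model()
  p <- single_pulse_protocol(intensity = 0.28, duration = 60, duty = 1)
  sim <- gen_roi_movie(scene, m, two_roi_planted(1, 0), p, two_roi_layout())
  tr <- extract_roi_trace(sim$movie, sim$rois[[1]])
  plateau <- (tr$values[90] - 100) / 100
  # independent closed form: amp_max * I / (I + half_sat)
  expect_equal(plateau, m$amp_max * 0.28 / (0.28 + m$half_sat), tolerance = 1e-3)
})

test_that("roi movie generation is deterministic for a fixed seed", {
  scene <- scene_params(image_height = 24, image_width = 42, n_frames = 15,
                        noise_sd = 5, seed = 99)
  mk <- function() gen_roi_movie(scene, demo_model(), two_roi_planted(1, 0.5),
                                 single_pulse_protocol(), two_roi_layout())
  expect_identical(mk()$movie$frames, mk()$movie$frames)
  # and does not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(mk()); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("overlapping or out-of-frame ROIs are layout errors", {
  scene <- scene_params(image_height = 24, image_width = 42, n_frames = 5)
  overlapping <- list(
    list(label = "A", center = c(12, 12), radius = 3, pre = "src", post = "A"),
    list(label = "B", center = c(12, 16), radius = 3, pre = "src", post = "B"))
  expect_error(gen_roi_movie(scene, demo_model(), two_roi_planted(),
                             single_pulse_protocol(), overlapping),
               class = "fcmap_layout_error")
  outside <- list(list(label = "A", center = c(2, 2), radius = 3,
                       pre = "src", post = "A"))
  expect_error(gen_roi_movie(scene, demo_model(), two_roi_planted(),
                             single_pulse_protocol(), outside),
               class = "fcmap_layout_error")
})

test_that("peak responses are nondecreasing across the six escalating pulses", {
  scene <- scene_params(image_height = 24, image_width = 42, frame_rate = 2.5,
                        n_frames = 525, baseline_fluorescence = 100)
  p <- gen_stimulus_protocol()
  sim <- gen_roi_movie(scene, demo_model(), two_roi_planted(1, 0.2), p,
                       two_roi_layout())
  gt <- sim$ground_truth[sim$ground_truth$roi_id == "A", ]
  peaks <- vapply(seq_along(p$onsets), function(k) {
    sel <- gt$time_s >= p$onsets[k] & gt$time_s <= p$onsets[k] + p$durations[k]
    max(gt$dff_true[sel])
  }, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("vibration epochs follow the 4 s x2, 8 s ISI, 10 kHz defaults", {
  v <- gen_vibration_epochs(100)
  expect_equal(nrow(v$epochs), 2)
  expect_equal(diff(v$epochs$onset_s), 12)   # 4 s epoch + 8 s ISI
  expect_equal(v$epochs$n_samples[1], 40000)
  expect_equal(v$waveforms[[1]][1], 0)       # sin(0)
  # waveform really is a sine at the requested frequency
  tt <- (0:39999) / 10000
  expect_equal(v$waveforms[[1]], sin(2 * pi * 100 * tt))

  expect_error(gen_vibration_epochs(0), class = "fcmap_invalid_parameter")
  expect_error(gen_vibration_epochs(6000, sample_rate = 10000),
               class = "fcmap_invalid_parameter")
})

test_that("leg video renders the trajectory it reports as ground truth", {
  sc <- leg_scene_params(angle_trajectory = rep(90, 4))
  v <- gen_leg_video(sc)
  expect_equal(v$truth$angles, rep(90, 4))
  expect_equal(v$movie$frames[1, , ], v$movie$frames[4, , ])

  # 180 deg/s sweep from the ~18 deg flexion floor
  traj <- seq(18, 180, by = 180 * (1 / 200))   # 180 deg/s at 200 fps
  sc2 <- leg_scene_params(angle_trajectory = traj)
  v2 <- gen_leg_video(sc2)
  expect_equal(diff(range(v2$truth$angles)), 162)
  expect_equal(diff(range(v2$truth$times)), 0.9, tolerance = 1e-9)
})

test_that("rendered pin orientation round-trips through thresholded moments", {
  sc <- leg_scene_params(angle_trajectory = 137, femur_axis_angle = 0,
                         hinge_sign = 1)
  v <- gen_leg_video(sc)
  mask <- binarize_pin(v$movie$frames[1, , ])
  fit <- ellipse_orientation(mask)
  # image orientation of the tibia axis is (180 - 137) = 43 deg
  expect_equal(fit$orientation, 43, tolerance = 0.5)
  expect_equal(angle_from_orientation(fit, 0, 1), 137, tolerance = 0.5)
})

test_that("pin leaving the frame names the offending frame", {
  sc <- leg_scene_params(joint_center = c(80, 150),
                         angle_trajectory = c(90, 90, 180))
  err <- tryCatch(gen_leg_video(sc), error = identity)
  expect_s3_class(err, "fcmap_render_error")
  expect_match(conditionMessage(err), "frame 3")
})

test_that("noiseless generated movies reproduce ground truth through the full preprocessing chain", {
  scene <- scene_params(image_height = 24, image_width = 42, frame_rate = 2.5,
                        n_frames = 150, baseline_fluorescence = 100)
  p <- gen_stimulus_protocol(intensities = c(0.12, 0.28), pulse_duration = 5,
                             inter_pulse = 20)
  sim <- gen_roi_movie(scene, demo_model(), two_roi_planted(1, 0.5), p,
                       two_roi_layout())
  movie <- apply_threshold(gaussian_smooth(sim$movie), "otsu")
  for (roi in sim$rois) {
    tr <- compute_dff(extract_roi_trace(movie, roi))
    gt <- sim$ground_truth$dff_true[sim$ground_truth$roi_id == roi$label]
    big <- gt > 0.05
    expect_true(all(abs(tr$values[big] - gt[big]) / gt[big] < 0.01))
  }
})
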