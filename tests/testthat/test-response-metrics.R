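dff_of <- function(values, dt = 0.4, t0 = 0) {
  dff_trace(values, t0 + (seq_along(values) - 1) * dt,
            baseline_value = 1, baseline_mode = "lowest-window")
}

test_that("peak response picks the window maximum, earliest on ties", {
  flat <- dff_of(rep(0, 50))
  k <- peak_response(flat, 2, 5)
  expect_equal(k$f_peak, 0)
  expect_equal(k$t_peak, 2)   # first frame inside the window

  tri <- dff_of(c(seq(0, 2, length.out = 11), seq(1.8, 0, length.out = 10)))
  k2 <- peak_response(tri, 0, 8)
  expect_equal(k2$f_peak, 2)
  expect_equal(k2$t_peak, 10 * 0.4)

  expect_error(peak_response(flat, 100, 5), class = "fcmap_data_error")
})

test_that("generated pulse responses match the analytic model maximum", {
  scene <- scene_params(image_height = 24, image_width = 42, frame_rate = 8.01,
                        n_frames = 400, baseline_fluorescence = 100)
  m <- demo_model()
  p <- single_pulse_protocol(intensity = 0.28, duration = 5, duty = 0.5)
  sim <- gen_roi_movie(scene, m, two_roi_planted(1, 0), p, two_roi_layout())
  tr <- compute_dff(extract_roi_trace(sim$movie, sim$rois[[1]]))
  k <- peak_response(tr, 0, 5 + 2)   # allow the indicator lag past offset
  analytic <- max(model_response(m, p, seq(0, 10, by = 1e-3)))
  expect_equal(k$f_peak, analytic, tolerance = 0.01)
})

test_that("half-rise of a linear ramp is half the ramp duration", {
  ramp <- dff_of(c(rep(0, 5), seq(0, 3, length.out = 11), rep(3, 20)))
  onset <- 5 * 0.4
  k <- rise_decay_times(ramp, onset, peak_response(ramp, onset, 10))
  expect_equal(k$t50_rise, 2, tolerance = 1e-9)    # 4 s ramp
  expect_true(is.na(k$t50_decay))                  # plateau never decays
})

test_that("half-decay of an exponential tail is tau * ln 2 within a frame", {
  dt <- 0.4
  for (tau in c(1, 2, 5)) {
    tt <- seq(0, 40, by = dt)
    v <- ifelse(tt < 2, tt / 2, exp(-(tt - 2) / tau))
    tr <- dff_trace(v, tt, 1, "lowest-window")
    k <- rise_decay_times(tr, 0, peak_response(tr, 0, 10))
    expect_equal(k$t50_decay, tau * log(2), tolerance = dt)
    expect_equal(k$t50_rise, 1, tolerance = dt)
  }
})

test_that("kinetics refuse non-excitatory responses", {
  neg <- dff_of(rep(-0.5, 80))
  expect_error(rise_decay_times(neg, 0, peak_response(neg, 0, 5)),
               class = "fcmap_undefined_kinetics")
  expect_error(adaptation_index(dff_of(rep(0, 80)), 0),
               class = "fcmap_undefined_index")
})

test_that("adaptation index hits its definitional anchors", {
  tt <- seq(0, 30, by = 0.5)   # 19 s falls exactly on a frame

  # full decay to baseline by 19 s -> index exactly 1
  decayed <- ifelse(tt < 1, tt, pmax(1 - (tt - 1) / 10, 0))
  k1 <- adaptation_index(dff_trace(decayed, tt, 1, "lowest-window"), 0)
  expect_identical(k1$adaptation_index, 1)
  expect_identical(k1$f_offset, 0)

  # flat plateau -> index exactly 0
  plateau <- ifelse(tt < 1, 1.5 * tt, 1.5)
  k2 <- adaptation_index(dff_trace(plateau, tt, 1, "lowest-window"), 0)
  expect_identical(k2$adaptation_index, 0)

  # growth to twice the in-window peak -> index -1
  grow <- pmin(tt / 1, 2)   # peaks at 1 inside a 1 s window, 2 by 19 s
  k3 <- adaptation_index(dff_trace(grow, tt, 1, "lowest-window"), 0,
                         stim_duration = 1)
  expect_identical(k3$adaptation_index, -1)

  # too-short trace errors
  expect_error(adaptation_index(dff_of(rep(1, 10)), 0), class = "fcmap_data_error")
})

test_that("adaptation index is invariant to trace rescaling and bounded for decaying traces", {
  dt <- 0.4
  tt <- seq(0, 25, by = dt)
  set.seed(8)
  for (i in 1:10) {
    peak <- runif(1, 0.5, 3)
    v <- ifelse(tt < 2, peak * tt / 2, peak * exp(-(tt - 2) / runif(1, 2, 20)))
    tr <- dff_trace(v, tt, 1, "lowest-window")
    k <- adaptation_index(tr, 0)
    ks <- adaptation_index(dff_trace(5 * v, tt, 1, "lowest-window"), 0)
    expect_equal(k$adaptation_index, ks$adaptation_index)
    # nonincreasing after the peak: index within [0, 1]
    expect_gte(k$adaptation_index, 0)
    expect_lte(k$adaptation_index, 1)
  }
})

test_that("crossing times are stable under 2x linear-interpolation resampling", {
  dt <- 0.4
  tt <- seq(0, 30, by = dt)
  v <- ifelse(tt < 3, tt / 3, exp(-(tt - 3) / 4))
  tr <- dff_trace(v, tt, 1, "lowest-window")
  tt2 <- seq(0, 30, by = dt / 2)
  tr2 <- dff_trace(approx(tt, v, tt2)$y, tt2, 1, "lowest-window")
  k <- rise_decay_times(tr, 0, peak_response(tr, 0, 10))
  k2 <- rise_decay_times(tr2, 0, peak_response(tr2, 0, 10))
  expect_lt(abs(k$t50_rise - k2$t50_rise), dt)
  expect_lt(abs(k$t50_decay - k2$t50_decay), dt)
})

test_that("measured adaptation matches the generating model's closed form", {
  # long enough after the pulse for the trace to return to true baseline,
  # so the lowest-window baseline is uncontaminated
  scene <- scene_params(image_height = 24, image_width = 42, frame_rate = 2.5,
                        n_frames = 115, baseline_fluorescence = 100)
  m <- gcamp_model(adaptation_tau = 6, adaptation_floor = 0.2)
  p <- single_pulse_protocol(intensity = 0.28, duration = 25, duty = 1)
  sim <- gen_roi_movie(scene, m, two_roi_planted(1, 0), p, two_roi_layout())
  tr <- compute_dff(extract_roi_trace(gaussian_smooth(sim$movie), sim$rois[[1]]))
  k <- adaptation_index(tr, 0, stim_duration = 19)

  # closed form, evaluated densely and independently of the frame grid
  amp <- m$amp_max * 0.28 / (0.28 + m$half_sat)
  tt <- seq(0, 25, by = 1e-3)
  lin <- 1 - (m$decay_tau * exp(-tt / m$decay_tau) -
                m$rise_tau * exp(-tt / m$rise_tau)) / (m$decay_tau - m$rise_tau)
  s <- 0.28 * lin
  r <- (m$amp_max * s / (s + m$half_sat)) *
    (0.2 + 0.8 * exp(-tt / 6))
  truth <- 1 - r[which.min(abs(tt - 19))] / max(r)
  expect_equal(k$adaptation_index, truth, tolerance = 0.02)
})

test_that("pixel-map capping flags strictly-above-cap pixels only", {
  mp <- matrix(c(0.5, 3.0, 3.01, 7, -0.2, 1), 2, 3)
  cm <- cap_pixel_map(mp)
  expect_equal(sum(cm$capped), 2)
  expect_true(is.na(cm$display[1, 2]))          # 3.01 capped
  expect_false(cm$capped[2, 1])                  # exactly 3.0 kept
  expect_equal(cm$display[!cm$capped], mp[!cm$capped])

  none <- cap_pixel_map(matrix(runif(9), 3, 3))
  expect_equal(sum(none$capped), 0)
  expect_equal(none$display, none$values)

  set.seed(2)
  z <- matrix(runif(400, 0, 6), 20, 20)
  expect_equal(sum(cap_pixel_map(z)$capped), sum(z > 3))
})

test_that("vibration tuning averages within fly before across flies", {
  one <- data.frame(fly = "f1", frequency = 100, response = c(1, 3))
  tc <- vibration_tuning(one)
  expect_equal(unname(tc$per_fly[1, 1]), 2)
  expect_equal(unname(tc$mean_response), 2)

  two <- data.frame(fly = rep(c("f1", "f2"), each = 1),
                    frequency = 100, response = c(1, 3))
  expect_equal(unname(vibration_tuning(two)$mean_response), 2)

  # equal rep counts: two-stage mean equals the grand mean
  set.seed(9)
  bal <- expand.grid(fly = paste0("f", 1:4), frequency = c(100, 400), rep = 1:3)
  bal$response <- runif(nrow(bal))
  tc2 <- vibration_tuning(bal)
  for (q in c(100, 400))
    expect_equal(unname(tc2$mean_response[as.character(q)]),
                 mean(bal$response[bal$frequency == q]))

  miss <- data.frame(fly = c("f1", "f1", "f2"), frequency = c(100, 200, 100),
                     response = 1)
  err <- tryCatch(vibration_tuning(miss), error = identity)
  expect_s3_class(err, "fcmap_data_error")
  expect_match(conditionMessage(err), "f2")
  expect_match(conditionMessage(err), "200")
})
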