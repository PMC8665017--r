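trial <- function(fly, pre, post, intensity, f_peak) {
  data.frame(fly_id = fly, pre_label = pre, post_label = post,
             intensity = intensity, f_peak = f_peak)
}

test_that("intensity-response curves average within fly before across flies", {
  one <- trial("f1", "club", "9Ba", 0.28, 1.5)
  cv <- intensity_response_curve(one)
  expect_equal(unname(cv$mean_f_peak), 1.5)

  two <- rbind(trial("f1", "club", "9Ba", 0.28, c(0.5, 1.5)),
               trial("f2", "club", "9Ba", 0.28, 3.0))
  cv2 <- intensity_response_curve(two)
  expect_equal(unname(cv2$mean_f_peak), 2.0)   # per-fly means 1 and 3
  expect_equal(unname(cv2$n_flies), 2)

  expect_error(intensity_response_curve(rbind(one, trial("f1", "claw", "9Ba", 0.28, 1))),
               class = "fcmap_invalid_parameter")
  expect_error(intensity_response_curve(one[0, ]), class = "fcmap_data_error")
})

test_that("noiseless saturating generator yields a nondecreasing curve matching the amplitude map", {
  scene <- scene_params(image_height = 24, image_width = 42, frame_rate = 2.5,
                        n_frames = 525, baseline_fluorescence = 100)
  m <- demo_model()
  p <- gen_stimulus_protocol()
  sim <- gen_roi_movie(scene, m, two_roi_planted(1, 0), p, two_roi_layout())
  tr <- compute_dff(extract_roi_trace(sim$movie, sim$rois[[1]]))
  rows <- lapply(seq_along(p$onsets), function(k) {
    kin <- peak_response(tr, p$onsets[k], p$durations[k])
    trial("f1", "club", "9Ba", p$intensities[k], kin$f_peak)
  })
  cv <- intensity_response_curve(do.call(rbind, rows))
  expect_true(all(diff(cv$mean_f_peak) >= 0))
  # each pulse peak is below (and tracks) the amplitude-map steady state
  amps <- steady_state_dff(m, cv$intensities, duty = p$duty)
  expect_true(all(cv$mean_f_peak <= amps * 1.001))
  expect_equal(unname(cv$mean_f_peak), unname(amps), tolerance = 0.25)
})

test_that("plateau-intensity selection picks the protocol value nearest 0.3", {
  expect_equal(select_plateau_intensity(c(0.02, 0.04, 0.12, 0.28, 0.37, 0.68)), 0.28)
  expect_equal(select_plateau_intensity(0.12), 0.12)
  expect_equal(select_plateau_intensity(c(0.2, 0.4)), 0.2)   # tie -> lower
})

test_that("matrix cells are two-stage means; untested pairs stay missing", {
  tr <- rbind(trial("f1", "club", "9Ba", 0.28, c(1, 2)),
              trial("f2", "club", "9Ba", 0.28, 4),
              trial("f1", "claw", "13Bb", 0.28, 0.5))
  m <- build_matrix(tr, 0.28)
  expect_equal(m$values["club", "9Ba"], (1.5 + 4) / 2)
  expect_equal(m$values["claw", "13Bb"], 0.5)
  expect_true(is.na(m$values["club", "13Bb"]))   # missing, never zero
  expect_equal(m$n_flies["club", "9Ba"], 2L)

  # permutation invariance over trials and fly relabeling
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(build_matrix(perm, 0.28)$values, m$values)
  relab <- tr
  relab$fly_id <- c("z9", "a1", "q7")[match(paste(tr$fly_id, tr$pre_label),
                                            unique(paste(tr$fly_id, tr$pre_label)))]
  expect_equal(unname(build_matrix(relab, 0.28)$values), unname(m$values))

  expect_error(build_matrix(rbind(tr, trial("f1", "club", "9Ba", 0.37, 1)), 0.28),
               class = "fcmap_data_error")
})

test_that("two-stage averaging equals the grand mean only under equal trial counts", {
  set.seed(21)
  flies <- paste0("f", 1:5)
  equal <- do.call(rbind, lapply(flies, function(f)
    trial(f, "club", "9Ba", 0.28, runif(3))))
  m <- build_matrix(equal, 0.28)
  expect_equal(m$values["club", "9Ba"], mean(equal$f_peak))

  unequal <- do.call(rbind, lapply(seq_along(flies), function(i)
    trial(flies[i], "club", "9Ba", 0.28, runif(i))))
  mu <- build_matrix(unequal, 0.28)
  oracle <- mean(vapply(flies, function(f)
    mean(unequal$f_peak[unequal$fly_id == f]), 0))
  expect_equal(mu$values["club", "9Ba"], oracle)
  expect_false(isTRUE(all.equal(mu$values["club", "9Ba"], mean(unequal$f_peak))))
})

test_that("segment map lives on the six-neuromere vocabulary", {
  tr <- rbind(trial("f1", "T1L", "T1L", 0.28, 2.0),
              trial("f1", "T1L", "T2R", 0.28, 1.2))
  m <- build_segment_map(tr, 0.28)
  expect_equal(dim(m$values), c(6, 6))
  expect_equal(rownames(m$values), c("T1L", "T1R", "T2L", "T2R", "T3L", "T3R"))
  nz <- which(!is.na(m$values), arr.ind = TRUE)
  expect_equal(nrow(nz), 2)   # exactly the stimulated/responding cells
  expect_equal(m$values["T1L", "T1L"], 2.0)
  expect_equal(m$values["T1L", "T2R"], 1.2)

  expect_error(build_segment_map(trial("f1", "T4L", "T1L", 0.28, 1), 0.28),
               class = "fcmap_data_error")
})

test_that("identity and off-diagonal planted segment maps are recovered end-to-end", {
  legs <- c("T1L", "T1R", "T2L", "T2R", "T3L", "T3R")
  gains <- diag(6) * 1.0
  dimnames(gains) <- list(legs, legs)
  gains["T1L", "T2R"] <- 0.7   # club-style contralateral crossing
  planted <- planted_connectivity(gains)
  m <- demo_model()
  p <- single_pulse_protocol(intensity = 0.28, duration = 5, duty = 0.5)
  scene <- scene_params(image_height = 24, image_width = 100, frame_rate = 2.5,
                        n_frames = 60, baseline_fluorescence = 100)
  rows <- list()
  for (leg in legs) {
    layout <- lapply(seq_along(legs), function(j)
      list(label = legs[j], center = c(12, 8 + 15 * (j - 1)), radius = 3,
           pre = leg, post = legs[j]))
    sim <- gen_roi_movie(scene, m, planted, p, layout)
    for (roi in sim$rois) {
      tr <- compute_dff(extract_roi_trace(sim$movie, roi))
      kin <- peak_response(tr, 0, 7)
      rows[[length(rows) + 1]] <- trial("f1", leg, roi$label, 0.28, kin$f_peak)
    }
  }
  rec <- build_segment_map(do.call(rbind, rows), 0.28)
  unit <- max(rec$values)
  above <- rec$values > unit / 2
  expect_equal(unname(above), unname(gains > 0.5))
})
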