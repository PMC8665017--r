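#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline (synthetic scene, GCaMP
#' model, planted connectivity, stimulus protocol, preprocessing and metric
#' parameters, leg-video scene, vibration tuning setup) into one object that
#' serializes losslessly to JSON. Defaults give a small, fast demo: two
#' proprioceptor subtypes driving three downstream cell classes over the
#' standard six-pulse escalating protocol.
#'
#' @param outdir output directory for all pipeline artifacts.
#' @param seed master seed; every per-movie seed derives from it.
#' @param n_flies number of synthetic flies.
#' @param pre_labels,post_labels stimulated-source and recorded-class label
#'   vocabularies.
#' @param gains planted gain matrix (`pre_labels` x `post_labels`); default
#'   a sparse club/claw-style pattern.
#' @param scene,model,protocol,leg,tuning named lists overriding the
#'   defaults of [scene_params()], [gcamp_model()],
#'   [gen_stimulus_protocol()], [leg_scene_params()] and the tuning demo
#'   (fields `frequencies`, `n_reps`, `peak_hz`, `amplitude`, `noise_sd`).
#' @param roi_radius ROI disk radius (px).
#' @param baseline_window,baseline_mode dF/F baseline parameters
#'   (see [compute_dff()]).
#' @param filter_size,filter_sigma spatial smoothing parameters
#'   (see [gaussian_smooth()]).
#' @param threshold `"otsu"` or an absolute value (see [apply_threshold()]).
#' @param offset_lag adaptation-index offset lag (s).
#' @param cap display cap for pixel maps (dF/F).
#' @param plateau_target plateau intensity target (mW/mm^2).
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("fcmap_run_"), seed = 1,
                       n_flies = 2,
                       pre_labels = c("club", "claw"),
                       post_labels = c("9Ba", "10Ba", "13Bb"),
                       gains = NULL,
                       scene = list(), model = list(), protocol = list(),
                       leg = list(), tuning = list(),
                       roi_radius = 3,
                       baseline_window = 10, baseline_mode = "lowest-window",
                       filter_size = 5, filter_sigma = 3,
                       threshold = "otsu", offset_lag = 19, cap = 3,
                       plateau_target = 0.3) {
  if (is.null(gains)) {
    gains <- matrix(0, length(pre_labels), length(post_labels),
                    dimnames = list(pre_labels, post_labels))
    gains[1, ] <- c(1.0, 0.8, 0)[seq_len(min(3, ncol(gains)))]
    if (nrow(gains) > 1 && ncol(gains) >= 3) gains[2, 3] <- 0.9
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_flies = as.integer(n_flies),
                 pre_labels = pre_labels, post_labels = post_labels,
                 gains = as.matrix(gains),
                 scene = scene, model = model, protocol = protocol,
                 leg = leg, tuning = tuning,
                 roi_radius = roi_radius,
                 baseline_window = baseline_window, baseline_mode = baseline_mode,
                 filter_size = filter_size, filter_sigma = filter_sigma,
                 threshold = threshold, offset_lag = offset_lag, cap = cap,
                 plateau_target = plateau_target),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$gains <- list(pre = rownames(config$gains), post = colnames(config$gains),
                  values = apply(config$gains, 1, as.list))
  jsonlite::write_json(c(list(schema_version = FCMAP_SCHEMA_VERSION), x),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop_data("config JSON not found at ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- matrix(unlist(x$gains$values), nrow = length(x$gains$pre), byrow = TRUE,
              dimnames = list(x$gains$pre, x$gains$post))
  run_config(outdir = x$outdir, seed = x$seed, n_flies = x$n_flies,
             pre_labels = x$gains$pre, post_labels = x$gains$post, gains = g,
             scene = as.list(x$scene), model = as.list(x$model),
             protocol = as.list(x$protocol), leg = as.list(x$leg),
             tuning = as.list(x$tuning),
             roi_radius = x$roi_radius,
             baseline_window = x$baseline_window, baseline_mode = x$baseline_mode,
             filter_size = x$filter_size, filter_sigma = x$filter_sigma,
             threshold = x$threshold, offset_lag = x$offset_lag, cap = x$cap,
             plateau_target = x$plateau_target)
}

config_protocol <- function(config) do.call(gen_stimulus_protocol, config$protocol)
config_model <- function(config) do.call(gcamp_model, config$model)

config_scene <- function(config, seed) {
  protocol <- config_protocol(config)
  # just enough frame to hold the ROI grid of config_layout plus margins
  spacing <- 2 * (config$roi_radius + 2) + 4
  n_cols <- min(length(config$post_labels), 4)
  n_rows <- ceiling(length(config$post_labels) / 4)
  defaults <- list(image_height = n_rows * spacing + config$roi_radius + 4,
                   image_width = n_cols * spacing + config$roi_radius + 4,
                   frame_rate = 2.5, baseline_fluorescence = 200,
                   noise_sd = 0, seed = seed)
  args <- utils::modifyList(defaults, config$scene)
  args$seed <- seed
  if (is.null(args$n_frames))
    args$n_frames <- ceiling((protocol$total_span + 25) * args$frame_rate)
  do.call(scene_params, args)
}

# One disk ROI per post class, laid out on a grid with margin-safe spacing.
config_layout <- function(config, pre) {
  spacing <- 2 * (config$roi_radius + 2) + 4
  lapply(seq_along(config$post_labels), function(j) {
    row <- 1 + (j - 1) %/% 4
    col <- 1 + (j - 1) %% 4
    list(label = config$post_labels[j],
         center = c(row * spacing, col * spacing),
         radius = config$roi_radius,
         pre = pre, post = config$post_labels[j])
  })
}

fly_seed <- function(config, fly, pre_idx) {
  (config$seed + 7919L * fly + 104729L * pre_idx) %% .Machine$integer.max
}

log_params <- function(stage, params) {
  message(stage, ": ",
          paste(names(params), vapply(params, function(v)
            paste(as.character(v), collapse = ","), ""), sep = "=", collapse = " "))
}

#' Simulate the demo dataset for a pipeline run
#'
#' Writes, under `config$outdir`: one 16-bit TIFF movie (plus JSON sidecar)
#' per fly and stimulated source, the shared ROI masks (JSON), the stimulus
#' protocol (JSON), the noiseless ground-truth dF/F (CSV), a rendered leg
#' video with its ground-truth angle trace, per-fly vibration responses
#' (CSV), and a provenance JSON (the full configuration) sufficient to
#' reproduce every file bit-identically.
#'
#' @param config a [run_config()].
#' @return The list of files written, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$outdir)) stop_data("cannot create output directory ", config$outdir)
  files <- character(0)
  protocol <- config_protocol(config)
  model <- config_model(config)
  planted <- planted_connectivity(config$gains)
  write_config_json(config, file.path(config$outdir, "provenance.json"))
  write_protocol_json(protocol, file.path(config$outdir, "protocol.json"))
  files <- c(files, "provenance.json", "protocol.json")

  truth_all <- list()
  for (fly in seq_len(config$n_flies)) {
    for (p in seq_along(config$pre_labels)) {
      pre <- config$pre_labels[p]
      scene <- config_scene(config, seed = fly_seed(config, fly, p))
      layout <- config_layout(config, pre)
      sim <- gen_roi_movie(scene, model, planted, protocol, layout)
      fn <- sprintf("movie_fly%d_%s.tif", fly, pre)
      write_movie_tiff(sim$movie, file.path(config$outdir, fn))
      files <- c(files, fn)
      if (fly == 1 && p == 1) {
        write_rois_json(sim$rois, file.path(config$outdir, "rois.json"))
        files <- c(files, "rois.json")
      }
      gt <- sim$ground_truth
      gt$fly <- fly; gt$pre_label <- pre
      truth_all[[length(truth_all) + 1]] <- gt
    }
  }
  gt <- do.call(rbind, truth_all)
  gt$time_s <- signif6(gt$time_s); gt$dff_true <- signif6(gt$dff_true)
  utils::write.csv(gt[, c("fly", "pre_label", "roi_id", "time_s", "dff_true")],
                   file.path(config$outdir, "ground_truth.csv"), row.names = FALSE)
  files <- c(files, "ground_truth.csv")

  # leg video: a swing through most of the physical joint range
  leg_defaults <- list(angle_trajectory = seq(18, 178, length.out = 60),
                       seed = config$seed)
  leg_scene <- do.call(leg_scene_params, utils::modifyList(leg_defaults, config$leg))
  leg <- gen_leg_video(leg_scene)
  write_movie_tiff(leg$movie, file.path(config$outdir, "leg_video.tif"))
  write_angle_csv(leg$truth, file.path(config$outdir, "leg_truth.csv"))
  files <- c(files, "leg_video.tif", "leg_truth.csv")

  # per-fly vibration responses: log-Gaussian tuning around peak_hz
  tun <- utils::modifyList(list(frequencies = c(100, 200, 400, 800),
                                n_reps = 2, peak_hz = 400, amplitude = 1,
                                noise_sd = 0.05), config$tuning)
  vib <- expand.grid(rep = seq_len(tun$n_reps), frequency = tun$frequencies,
                     fly = seq_len(config$n_flies))
  vib$response <- with_seed(config$seed + 13L, {
    mu <- tun$amplitude * exp(-(log2(vib$frequency / tun$peak_hz))^2 / 2)
    pmax(mu + stats::rnorm(nrow(vib), sd = tun$noise_sd), 0)
  })
  vib$response <- signif6(vib$response)
  utils::write.csv(vib[, c("fly", "frequency", "rep", "response")],
                   file.path(config$outdir, "vibration_responses.csv"),
                   row.names = FALSE)
  files <- c(files, "vibration_responses.csv")
  log_params("simulate", list(outdir = config$outdir, seed = config$seed,
                              n_flies = config$n_flies,
                              pre = config$pre_labels, post = config$post_labels))
  invisible(files)
}

require_upstream <- function(path, stage_needed) {
  if (!file.exists(path))
    stop_data("missing upstream artifact ", basename(path),
              "; run the '", stage_needed, "' stage first",
              class = "fcmap_missing_upstream")
  path
}

#' Run one pipeline stage
#'
#' Stages: `"dff"` (movies -> per-ROI dF/F traces), `"metrics"` (traces ->
#' kinetics and trial records at the plateau intensity), `"connectivity"`
#' (trials -> matrix CSV and heatmap), `"track"` (leg video -> joint-angle
#' CSV), `"tuning"` (vibration responses -> tuning curve CSV). Each stage
#' reads its inputs from `config$outdir`, errors if the upstream stage has
#' not been run, writes its outputs there, and logs every resolved
#' parameter.
#'
#' @param stage one of `"dff"`, `"metrics"`, `"connectivity"`, `"track"`,
#'   `"tuning"`.
#' @param config a [run_config()].
#' @return The stage's main result object, invisibly.
#' @export
run_stage <- function(stage = c("dff", "metrics", "connectivity", "track", "tuning"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  od <- config$outdir
  switch(stage,
    dff = {
      rois <- read_rois_json(require_upstream(file.path(od, "rois.json"), "simulate"))
      log_params("dff", list(filter_size = config$filter_size,
                             filter_sigma = config$filter_sigma,
                             threshold = config$threshold,
                             baseline_window = config$baseline_window,
                             baseline_mode = config$baseline_mode))
      rows <- list()
      for (fly in seq_len(config$n_flies)) {
        for (pre in config$pre_labels) {
          fn <- file.path(od, sprintf("movie_fly%d_%s.tif", fly, pre))
          movie <- read_movie_tiff(require_upstream(fn, "simulate"))
          movie <- gaussian_smooth(movie, config$filter_size, config$filter_sigma)
          movie <- apply_threshold(movie, config$threshold)
          for (roi in rois) {
            tr <- compute_dff(extract_roi_trace(movie, roi),
                              window = config$baseline_window,
                              mode = config$baseline_mode)
            rows[[length(rows) + 1]] <- data.frame(
              fly = fly, pre_label = pre, roi_id = roi$label,
              time_s = signif6(tr$times), dff = signif6(tr$values),
              baseline = signif6(tr$baseline_value))
          }
        }
      }
      out <- do.call(rbind, rows)
      utils::write.csv(out, file.path(od, "dff.csv"), row.names = FALSE)
      invisible(out)
    },
    metrics = {
      dff <- utils::read.csv(require_upstream(file.path(od, "dff.csv"), "dff"))
      protocol <- read_protocol_json(require_upstream(file.path(od, "protocol.json"),
                                                      "simulate"))
      intensity <- select_plateau_intensity(protocol$intensities,
                                            config$plateau_target)
      k <- which(protocol$intensities == intensity)[1]
      onset <- protocol$onsets[k]; dur <- protocol$durations[k]
      log_params("metrics", list(plateau_intensity = intensity,
                                 pulse_onset = onset, pulse_duration = dur,
                                 offset_lag = config$offset_lag))
      combos <- unique(dff[, c("fly", "pre_label", "roi_id")])
      out <- list()
      for (i in seq_len(nrow(combos))) {
        sel <- dff$fly == combos$fly[i] & dff$pre_label == combos$pre_label[i] &
          dff$roi_id == combos$roi_id[i]
        tr <- dff_trace(dff$dff[sel], dff$time_s[sel],
                        baseline_value = dff$baseline[sel][1],
                        baseline_mode = config$baseline_mode,
                        label = combos$roi_id[i])
        kin <- peak_response(tr, onset, dur)
        kin <- tryCatch(rise_decay_times(tr, onset, kin),
                        fcmap_undefined_kinetics = function(e) kin)
        adapt <- if (max(tr$times) >= onset + config$offset_lag)
          tryCatch(adaptation_index(tr, onset, stim_duration = dur,
                                    offset_lag = config$offset_lag),
                   fcmap_undefined_index = function(e) NULL)
        out[[i]] <- data.frame(
          fly_id = combos$fly[i], pre_label = combos$pre_label[i],
          post_label = combos$roi_id[i], intensity = intensity,
          f_peak = signif6(kin$f_peak), t_peak = signif6(kin$t_peak),
          t50_rise = signif6(kin$t50_rise), t50_decay = signif6(kin$t50_decay),
          f_offset = if (is.null(adapt)) NA_real_ else signif6(adapt$f_offset),
          adaptation_index = if (is.null(adapt)) NA_real_
                             else signif6(adapt$adaptation_index))
      }
      out <- do.call(rbind, out)
      utils::write.csv(out, file.path(od, "kinetics.csv"), row.names = FALSE)
      utils::write.csv(out[, c("fly_id", "pre_label", "post_label",
                               "intensity", "f_peak")],
                       file.path(od, "trials.csv"), row.names = FALSE)
      invisible(out)
    },
    connectivity = {
      trials <- utils::read.csv(require_upstream(file.path(od, "trials.csv"),
                                                 "metrics"))
      log_params("connectivity", list(intensity = trials$intensity[1],
                                      pre = config$pre_labels,
                                      post = config$post_labels))
      mat <- build_matrix(trials, trials$intensity[1],
                          pre_levels = config$pre_labels,
                          post_levels = config$post_labels)
      write_matrix_csv(mat, file.path(od, "connectivity_matrix.csv"))
      grDevices::png(file.path(od, "connectivity_matrix.png"), 600, 480)
      plot(mat)
      grDevices::dev.off()
      invisible(mat)
    },
    track = {
      movie <- read_movie_tiff(require_upstream(file.path(od, "leg_video.tif"),
                                                "simulate"))
      leg_defaults <- list(femur_axis_angle = 0, hinge_sign = 1)
      leg <- utils::modifyList(leg_defaults, config$leg)
      log_params("track", list(femur_axis_angle = leg$femur_axis_angle,
                               hinge_sign = leg$hinge_sign))
      angles <- track_leg_video(movie, leg$femur_axis_angle, leg$hinge_sign)
      write_angle_csv(angles, file.path(od, "tracked_angles.csv"))
      invisible(angles)
    },
    tuning = {
      vib <- utils::read.csv(require_upstream(file.path(od, "vibration_responses.csv"),
                                              "simulate"))
      log_params("tuning", list(frequencies = sort(unique(vib$frequency)),
                                n_flies = length(unique(vib$fly))))
      curve <- vibration_tuning(vib)
      df <- data.frame(frequency = curve$frequencies,
                       mean_response = signif6(unname(curve$mean_response)))
      for (f in rownames(curve$per_fly))
        df[[paste0("fly_", f)]] <- signif6(curve$per_fly[f, ])
      utils::write.csv(df, file.path(od, "tuning_curve.csv"), row.names = FALSE)
      invisible(curve)
    })
}

#' Run the full synthetic demo end-to-end
#'
#' [run_simulate()] followed by every analysis stage; returns the stage
#' results (including the recovered connectivity matrix) for inspection.
#'
#' @param config a [run_config()].
#' @return A named list with the `dff`, `metrics`, `connectivity`, `track`
#'   and `tuning` stage results.
#' @export
run_demo <- function(config = run_config()) {
  run_simulate(config)
  res <- list()
  for (s in c("dff", "metrics", "connectivity", "track", "tuning"))
    res[[s]] <- run_stage(s, config)
  res
}
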