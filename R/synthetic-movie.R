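#' Scene parameters for synthetic calcium-imaging movies
#'
#' @param image_height,image_width frame size in pixels.
#' @param frame_rate acquisition rate (frames/s), > 0. The default 2.5 fps
#'   matches standard functional-connectivity imaging; 8.01 Hz is typical for
#'   imaging during controlled leg movements.
#' @param n_frames number of frames, >= 1.
#' @param baseline_fluorescence resting fluorescence of labelled tissue
#'   (arbitrary units), > 0.
#' @param background_fluorescence fluorescence outside labelled regions;
#'   default one tenth of `baseline_fluorescence`.
#' @param noise_sd per-pixel, per-frame Gaussian noise SD (same units), >= 0.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_height = 64, image_width = 64,
                         frame_rate = 2.5, n_frames = 100,
                         baseline_fluorescence = 200,
                         background_fluorescence = NULL,
                         noise_sd = 0, seed = 1L) {
  check_scalar(image_height, "image_height", positive = TRUE)
  check_scalar(image_width, "image_width", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  check_scalar(baseline_fluorescence, "baseline_fluorescence", positive = TRUE)
  if (is.null(background_fluorescence))
    background_fluorescence <- baseline_fluorescence / 10
  check_scalar(background_fluorescence, "background_fluorescence", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 baseline_fluorescence = baseline_fluorescence,
                 background_fluorescence = background_fluorescence,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_params")
}

#' Planted ground-truth connectivity
#'
#' A pre-source x post-class grid of nonnegative gains used by the movie
#' generator: an ROI assigned to pair (pre, post) responds with the model
#' response scaled by `gains[pre, post]`.
#'
#' @param gains numeric matrix of finite gains >= 0.
#' @param pre_labels,post_labels unique row/column labels (e.g. FeCO subtype
#'   or stimulated leg for rows; hemilineage class or neuromere for columns).
#'   Taken from `dimnames(gains)` when omitted.
#' @return An object of class `planted_connectivity`.
#' @export
planted_connectivity <- function(gains, pre_labels = rownames(gains),
                                 post_labels = colnames(gains)) {
  gains <- as.matrix(gains)
  if (any(!is.finite(gains)) || any(gains < 0))
    stop_invalid("gains must be finite and >= 0")
  if (is.null(pre_labels) || is.null(post_labels))
    stop_invalid("pre_labels and post_labels are required (or set dimnames on gains)")
  if (anyDuplicated(pre_labels) || anyDuplicated(post_labels))
    stop_invalid("labels must be unique")
  if (length(pre_labels) != nrow(gains) || length(post_labels) != ncol(gains))
    stop_invalid("label lengths must match the gain matrix")
  dimnames(gains) <- list(pre_labels, post_labels)
  structure(list(gains = gains), class = "planted_connectivity")
}

planted_gain <- function(planted, pre, post) {
  g <- planted$gains
  if (!(pre %in% rownames(g)) || !(post %in% colnames(g)))
    stop_invalid("unknown (pre, post) pair: ", pre, " -> ", post)
  g[pre, post]
}

#' Generate a synthetic ROI movie with ground truth
#'
#' Renders a movie in which each ROI's pixels follow
#' `baseline * (1 + g * r(t))` plus optional Gaussian noise (floored at 0),
#' where `r(t)` is the model response to the protocol and `g` the planted
#' gain for the ROI's (pre, post) pair. Pixels outside ROIs sit at the
#' scene's background level. Each ROI's signal is painted onto the ROI disk
#' dilated by `margin` pixels, so that subsequent spatial smoothing with a
#' small kernel leaves ROI-interior pixel values untouched; the ROI masks
#' returned for extraction are the undilated disks.
#'
#' @param scene a [scene_params()].
#' @param model a [gcamp_model()].
#' @param planted a [planted_connectivity()].
#' @param protocol a [gen_stimulus_protocol()].
#' @param roi_layout list of entries `list(label =, center =, radius =,
#'   pre =, post =)` placing disk ROIs and assigning each to a planted pair.
#' @param margin dilation (pixels) of the painted signal region around each
#'   ROI disk; default 2, the half-width of the standard 5x5 smoothing
#'   kernel.
#' @return A list with `movie` ([imaging_movie()]), `rois` (list of
#'   [roi_mask()]), `ground_truth` (data.frame `time_s`, `roi_id`,
#'   `dff_true` of the noiseless dF/F per ROI), and `layout` (the input
#'   layout).
#' @export
gen_roi_movie <- function(scene, model, planted, protocol, roi_layout,
                          margin = 2) {
  stopifnot(inherits(scene, "scene_params"), inherits(model, "gcamp_model"),
            inherits(planted, "planted_connectivity"),
            inherits(protocol, "stim_protocol"))
  if (length(roi_layout) < 1L) stop_invalid("roi_layout must be nonempty")
  h <- scene$image_height; w <- scene$image_width
  nt <- scene$n_frames
  times <- (seq_len(nt) - 1) / scene$frame_rate
  r_t <- model_response(model, protocol, times)

  rois <- vector("list", length(roi_layout))
  painted <- vector("list", length(roi_layout))
  claimed <- matrix(FALSE, h, w)
  for (i in seq_along(roi_layout)) {
    spec <- roi_layout[[i]]
    pad_r <- spec$radius + margin
    if (spec$center[1] - pad_r < 1 || spec$center[1] + pad_r > h ||
        spec$center[2] - pad_r < 1 || spec$center[2] + pad_r > w)
      stop_data("ROI '", spec$label, "' (with its ", margin,
                "-px margin) exceeds the frame", class = "fcmap_layout_error")
    rois[[i]] <- roi_disk(spec$label, spec$center, spec$radius)
    pad <- roi_disk(spec$label, spec$center, pad_r)
    idx <- pad$pixels[, 1] + (pad$pixels[, 2] - 1) * h
    if (any(claimed[idx]))
      stop_data("ROI '", spec$label, "' overlaps another ROI (margins included)",
                class = "fcmap_layout_error")
    claimed[idx] <- TRUE
    painted[[i]] <- idx
  }

  base_frame <- matrix(scene$background_fluorescence, h, w)
  frames <- array(0, dim = c(nt, h, w))
  truth <- vector("list", length(roi_layout))
  for (i in seq_along(roi_layout)) {
    spec <- roi_layout[[i]]
    g <- planted_gain(planted, spec$pre, spec$post)
    truth[[i]] <- data.frame(time_s = times, roi_id = spec$label,
                             dff_true = g * r_t)
  }
  for (t in seq_len(nt)) {
    fr <- base_frame
    for (i in seq_along(roi_layout)) {
      fr[painted[[i]]] <- scene$baseline_fluorescence * (1 + truth[[i]]$dff_true[t])
    }
    frames[t, , ] <- fr
  }
  if (scene$noise_sd > 0) {
    frames <- with_seed(scene$seed, {
      pmax(frames + array(stats::rnorm(length(frames), sd = scene$noise_sd),
                          dim = dim(frames)), 0)
    })
  }
  movie <- imaging_movie(frames, frame_interval = 1 / scene$frame_rate,
                         metadata = list(kind = "synthetic_roi_movie",
                                         seed = scene$seed))
  list(movie = movie, rois = rois,
       ground_truth = do.call(rbind, truth), layout = roi_layout)
}
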