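#' Spatially smooth a movie with a Gaussian kernel
#'
#' Convolves each frame independently with a normalized `size` x `size`
#' Gaussian kernel (default 5 x 5, sigma 3 px, the standard denoising step
#' before dF/F extraction). Frame edges use reflect padding, which preserves
#' constant images and avoids dark-edge artifacts. Frames never mix: the
#' output at frame `t` depends only on the input frame `t`.
#'
#' @param movie an [imaging_movie()].
#' @param size odd kernel edge length in pixels.
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return A smoothed [imaging_movie()] of the same shape; the kernel
#'   parameters are recorded in the metadata.
#' @export
gaussian_smooth <- function(movie, size = 5, sigma = 3) {
  stopifnot(inherits(movie, "imaging_movie"))
  check_scalar(size, "size", positive = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  if (size %% 2 != 1) stop_invalid("size must be odd")
  g <- gaussian_kernel_1d(size, sigma)
  frames <- convolve_axis(movie$frames, g, axis = 2)
  frames <- convolve_axis(frames, g, axis = 3)
  md <- movie$metadata
  md$smooth <- list(size = size, sigma = sigma, padding = "reflect")
  imaging_movie(frames, movie$frame_interval, movie$start_time, md)
}

# Normalized 1-D Gaussian taps; the 2-D kernel is their outer product,
# so the separable passes reproduce the full normalized size x size kernel.
gaussian_kernel_1d <- function(size, sigma) {
  hw <- (size - 1) / 2
  g <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  g / sum(g)
}

# Convolve a [time, row, col] array along `axis` (2 = rows, 3 = cols) with
# symmetric (edge-duplicating) reflect padding.
convolve_axis <- function(arr, g, axis) {
  n <- dim(arr)[axis]
  hw <- (length(g) - 1) / 2
  if (n == 1) return(arr)  # nothing to mix along a singleton axis
  refl <- function(i) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- array(0, dim = dim(arr))
  for (j in seq_along(g)) {
    idx <- refl(seq_len(n) + (j - 1 - hw))
    sl <- if (axis == 2) arr[, idx, , drop = FALSE] else arr[, , idx, drop = FALSE]
    out <- out + g[j] * sl
  }
  out
}

#' Threshold a movie to suppress background
#'
#' Sets pixels strictly below the threshold to zero, leaving others
#' unchanged. With `threshold = "otsu"` the threshold is chosen by
#' maximizing the between-class variance over a 256-bin intensity histogram
#' (Otsu's criterion), pooled over the whole movie by default so the
#' background/tissue split does not drift with stimulus-evoked brightening
#' (`otsu_scope = "frame"` recomputes it per frame instead). The
#' threshold(s) actually applied are recorded in the movie metadata.
#'
#' @param movie an [imaging_movie()].
#' @param threshold nonnegative numeric threshold (fluorescence units), or
#'   `"otsu"` for the automatic choice.
#' @param otsu_scope `"movie"` (one pooled threshold, default) or
#'   `"frame"` (one per frame); only used in automatic mode.
#' @return A thresholded [imaging_movie()].
#' @export
apply_threshold <- function(movie, threshold = "otsu",
                            otsu_scope = c("movie", "frame")) {
  stopifnot(inherits(movie, "imaging_movie"))
  otsu_scope <- match.arg(otsu_scope)
  frames <- movie$frames
  nt <- dim(frames)[1]
  if (identical(threshold, "otsu") && otsu_scope == "movie") {
    used <- otsu_threshold(frames)
    frames[frames < used] <- 0
  } else if (identical(threshold, "otsu")) {
    used <- numeric(nt)
    for (t in seq_len(nt)) {
      thr <- otsu_threshold(frames[t, , ])
      used[t] <- thr
      fr <- frames[t, , ]
      fr[fr < thr] <- 0
      frames[t, , ] <- fr
    }
  } else {
    check_scalar(threshold, "threshold", nonneg = TRUE)
    used <- threshold
    frames[frames < threshold] <- 0
  }
  md <- movie$metadata
  md$threshold <- list(mode = if (identical(threshold, "otsu")) "otsu" else "absolute",
                       used = used)
  imaging_movie(frames, movie$frame_interval, movie$start_time, md)
}

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over histogram split points
#' (256 bins spanning the observed range). Returns the bin edge separating
#' the two classes; for a bimodal image it falls between the modes.
#'
#' @param x numeric matrix or vector of intensities.
#' @param n_bins number of histogram bins.
#' @return The threshold (same units as `x`).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu_total <- cm[n_bins]
  # between-class variance for a split after each bin
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_total * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(bcv)
  edges[k + 1]
}

#' Extract a raw fluorescence trace from an ROI
#'
#' Per-frame mean intensity over the ROI pixels, on the movie's timebase.
#' Pixels zeroed by a prior threshold still participate in the mean, so ROI
#' geometry is fixed across frames.
#'
#' @param movie an [imaging_movie()].
#' @param roi an [roi_mask()].
#' @return A list of class `fluor_trace` with `values`, `times`, `label`.
#' @export
extract_roi_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "imaging_movie"), inherits(roi, "roi_mask"))
  d <- dim(movie$frames)
  if (!roi_in_bounds(roi, d[2], d[3]))
    stop_data("ROI '", roi$label, "' exceeds the frame bounds")
  idx <- roi$pixels[, 1] + (roi$pixels[, 2] - 1) * d[2]
  nt <- d[1]
  flat <- matrix(movie$frames, nrow = nt)  # [time, row*col]
  values <- rowMeans(flat[, idx, drop = FALSE])
  structure(list(values = values, times = frame_times(movie), label = roi$label),
            class = "fluor_trace")
}

#' dF/F trace container
#'
#' @param values dF/F per frame (dimensionless).
#' @param times frame times (s), strictly increasing.
#' @param baseline_value baseline fluorescence used, > 0.
#' @param baseline_mode `"lowest-window"` or `"initial-window"`.
#' @param label optional ROI label.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(values, times, baseline_value, baseline_mode, label = NULL) {
  if (length(values) != length(times))
    stop_invalid("values and times must have equal length")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  check_scalar(baseline_value, "baseline_value", positive = TRUE)
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 baseline_value = baseline_value,
                 baseline_mode = baseline_mode, label = label),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dF/F trace%s: %d frames over %g s, baseline %s (%s)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$values), diff(range(x$times)),
              fmt_num(x$baseline_value), x$baseline_mode))
  cat(sprintf("  range: %s to %s\n", fmt_num(min(x$values)), fmt_num(max(x$values))))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = expression(Delta * F / F), ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}

#' Compute dF/F from a raw fluorescence trace
#'
#' The baseline is either the lowest mean over all contiguous `window`-frame
#' windows of the trial (`"lowest-window"`, stride 1, earliest window on
#' ties) or the mean of the first `window` frames (`"initial-window"`, for
#' signals that are reduced below rest by the stimulus). dF/F is
#' `(F - baseline) / baseline`.
#'
#' @param trace a `fluor_trace` from [extract_roi_trace()], or a numeric
#'   vector of raw fluorescence.
#' @param window baseline window length in frames (default 10).
#' @param mode baseline mode, `"lowest-window"` (default) or
#'   `"initial-window"`.
#' @param times frame times, required when `trace` is a bare numeric vector.
#' @return A [dff_trace()].
#' @export
compute_dff <- function(trace, window = 10, mode = c("lowest-window", "initial-window"),
                        times = NULL) {
  mode <- match.arg(mode)
  if (inherits(trace, "fluor_trace")) {
    values <- trace$values
    times <- trace$times
    label <- trace$label
  } else {
    values <- as.numeric(trace)
    if (is.null(times)) times <- seq_along(values) - 1
    label <- NULL
  }
  check_scalar(window, "window", positive = TRUE)
  n <- length(values)
  if (n < window)
    stop_data("trace has ", n, " frames, shorter than the ", window,
              "-frame baseline window")
  if (mode == "lowest-window") {
    cs <- cumsum(c(0, values))
    means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
    baseline <- means[which.min(means)]  # which.min takes the earliest tie
  } else {
    baseline <- mean(values[seq_len(window)])
  }
  if (baseline <= 0)
    stop_data("degenerate baseline (", fmt_num(baseline),
              " <= 0); cannot form dF/F", class = "fcmap_degenerate_baseline")
  dff_trace((values - baseline) / baseline, times, baseline, mode, label)
}
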