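#' Imaging movie container
#'
#' A time-ordered stack of grayscale frames with a regular timebase.
#'
#' @param frames 3-D numeric array `[time, row, col]` of nonnegative, finite
#'   fluorescence intensities (arbitrary units).
#' @param frame_interval time between successive frames (s), > 0.
#' @param start_time acquisition time of the first frame (s).
#' @param metadata free-form named list (fly id, cell class, neuromere,
#'   processing provenance, ...).
#' @return An object of class `imaging_movie`.
#' @export
imaging_movie <- function(frames, frame_interval, start_time = 0, metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_invalid("frames must be a 3-D array [time, row, col]")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop_invalid("frame intensities must be finite and >= 0")
  check_scalar(frame_interval, "frame_interval", positive = TRUE)
  check_scalar(start_time, "start_time")
  structure(list(frames = frames, frame_interval = frame_interval,
                 start_time = start_time, metadata = metadata),
            class = "imaging_movie")
}

#' Frame timestamps of a movie
#'
#' Frame `k` (0-based) is stamped at `start_time + k * frame_interval`.
#'
#' @param movie an [imaging_movie()].
#' @return Numeric vector of times (s), one per frame.
#' @export
frame_times <- function(movie) {
  stopifnot(inherits(movie, "imaging_movie"))
  movie$start_time + (seq_len(dim(movie$frames)[1]) - 1) * movie$frame_interval
}

#' @export
print.imaging_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Imaging movie: %d frames of %d x %d px, %g s/frame (%.4g fps)\n",
              d[1], d[2], d[3], x$frame_interval, 1 / x$frame_interval))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' ROI mask
#'
#' A labelled set of pixel positions over which traces are averaged.
#'
#' @param label character label for the ROI.
#' @param pixels two-column integer matrix of (row, col) positions, 1-based.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) != 2L)
    stop_invalid("pixels must be a nonempty 2-column (row, col) matrix")
  if (any(pixels < 1) || any(pixels != round(pixels)))
    stop_invalid("pixel positions must be positive integers")
  dimnames(pixels) <- list(NULL, c("row", "col"))
  structure(list(label = as.character(label), pixels = pixels), class = "roi_mask")
}

#' Disk-shaped ROI
#'
#' @param label character label.
#' @param center numeric (row, col) center, 1-based pixel coordinates.
#' @param radius disk radius in pixels; a pixel belongs to the disk when its
#'   center lies within `radius` of `center`.
#' @return An [roi_mask()].
#' @export
roi_disk <- function(label, center, radius) {
  check_scalar(radius, "radius", positive = TRUE)
  r0 <- center[1]; c0 <- center[2]
  rows <- seq(floor(r0 - radius), ceiling(r0 + radius))
  cols <- seq(floor(c0 - radius), ceiling(c0 + radius))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - r0)^2 + (grid$col - c0)^2 <= radius^2
  roi_mask(label, as.matrix(grid[keep, , drop = FALSE]))
}

roi_in_bounds <- function(roi, nrow, ncol) {
  all(roi$pixels[, 1] >= 1 & roi$pixels[, 1] <= nrow &
        roi$pixels[, 2] >= 1 & roi$pixels[, 2] <= ncol)
}
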