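#' Joint-angle trace container
#'
#' @param times sample times (s), strictly increasing.
#' @param angles femur-tibia joint angles (degrees) in `[0, 180]`.
#' @param source_rate sampling rate the angles came from (frames/s).
#' @param metadata free-form named list.
#' @return An object of class `angle_trace`.
#' @export
angle_trace <- function(times, angles, source_rate, metadata = list()) {
  if (length(times) != length(angles))
    stop_invalid("times and angles must have equal length")
  if (length(times) == 0) stop_invalid("empty angle trace")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (any(angles < 0 | angles > 180))
    stop_invalid("angles must lie within [0, 180] degrees")
  structure(list(times = as.numeric(times), angles = as.numeric(angles),
                 source_rate = source_rate, metadata = metadata),
            class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("Angle trace: %d samples over %g s (source %g fps), range %s-%s deg\n",
              length(x$angles), diff(range(x$times)), x$source_rate,
              fmt_num(min(x$angles)), fmt_num(max(x$angles))))
  invisible(x)
}

#' @export
plot.angle_trace <- function(x, ...) {
  graphics::plot(x$times, x$angles, type = "l", xlab = "time (s)",
                 ylab = "femur-tibia angle (deg)", ylim = c(0, 180), ...)
  invisible(x)
}

#' Binarize the pin in a video frame
#'
#' The pin is painted dark on a bright background, so the mask is the set of
#' pixels strictly darker than the threshold. The default threshold is the
#' midpoint of the robust intensity range (1st to 99th percentile), which
#' separates the two modes of a well-lit pin scene without being dragged by
#' extreme noise values. By default only the largest 8-connected component
#' is kept, so isolated noise speckles far from the pin cannot corrupt the
#' second moments. Set `dark_pin = FALSE` for inverted-contrast frames
#' (bright pin): the same mask is then the pixels brighter than threshold.
#'
#' @param frame numeric intensity matrix.
#' @param threshold numeric threshold, or `NULL` for the robust midpoint.
#' @param dark_pin logical; is the pin darker than the background?
#' @param keep_largest keep only the largest connected component.
#' @return Logical matrix, `TRUE` on pin pixels.
#' @export
binarize_pin <- function(frame, threshold = NULL, dark_pin = TRUE,
                         keep_largest = TRUE) {
  frame <- as.matrix(frame)
  if (any(!is.finite(frame))) stop_invalid("frame must be finite")
  if (is.null(threshold)) {
    q <- stats::quantile(frame, c(0.01, 0.99), names = FALSE)
    threshold <- mean(q)
  }
  mask <- if (dark_pin) frame < threshold else frame > threshold
  if (!any(mask))
    stop_data("no pin detected: no pixels beyond threshold ", fmt_num(threshold),
              class = "fcmap_no_pin")
  if (keep_largest) mask <- largest_component(mask)
  mask
}

# Largest 8-connected component of a logical mask (flood fill over the
# mask pixels only; masks are small relative to the frame).
largest_component <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(mask)
  h <- nrow(mask)
  labels <- integer(length(idx))
  names(labels) <- idx
  pos <- stats::setNames(seq_along(idx), idx)
  current <- 0L
  offsets <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  row_of <- ((idx - 1L) %% h) + 1L
  for (s in seq_along(idx)) {
    if (labels[s] > 0L) next
    current <- current + 1L
    queue <- s
    labels[s] <- current
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- idx[p] + offsets
      # drop neighbours that wrap across matrix columns
      nb_ok <- abs(((nb - 1L) %% h) + 1L - row_of[p]) <= 1L
      nb <- nb[nb_ok]
      hits <- pos[as.character(nb)]
      hits <- hits[!is.na(hits)]
      new <- hits[labels[hits] == 0L]
      labels[new] <- current
      queue <- c(queue, new)
    }
  }
  best <- which.max(tabulate(labels))
  out <- mask & FALSE
  out[idx[labels == best]] <- TRUE
  out
}

#' Equivalent-ellipse orientation of a binary mask
#'
#' Computes the centroid and normalized second central moments of the mask
#' pixels and reports the orientation of the long axis of the ellipse with
#' the same second moments. Moments are taken in a right-handed image frame
#' (x = column, y = -row), so orientation is in degrees from the +column
#' axis, increasing toward decreasing row, mapped to `[0, 180)`.
#'
#' @param mask logical matrix (or 2-column (row, col) matrix of pixel
#'   positions).
#' @return An object of class `ellipse_fit`: `centroid` (row, col), `mu20`,
#'   `mu02`, `mu11` (x/y central moments per pixel), `orientation`
#'   (degrees), `axis_ratio` (major/minor, >= 1).
#' @export
ellipse_orientation <- function(mask) {
  if (is.logical(mask) || (is.matrix(mask) && ncol(mask) != 2)) {
    pix <- which(mask != 0, arr.ind = TRUE)
  } else {
    pix <- as.matrix(mask)
  }
  if (nrow(pix) < 2)
    stop_data("mask must contain at least two pixels")
  x <- pix[, 2]
  y <- -pix[, 1]
  # 1/12 adds each pixel's own unit-square variance, as in standard
  # region-props ellipse fitting; it stabilizes thin masks.
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  if (abs(mu20 - mu02) < 1e-12 && abs(mu11) < 1e-12)
    stop_data("orientation undefined: isotropic second-moment matrix",
              class = "fcmap_isotropic_mask")
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta <- theta %% 180
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  lam1 <- (mu20 + mu02 + common) / 2
  lam2 <- (mu20 + mu02 - common) / 2
  structure(list(centroid = c(row = mean(pix[, 1]), col = mean(pix[, 2])),
                 mu20 = mu20, mu02 = mu02, mu11 = mu11,
                 orientation = theta,
                 axis_ratio = sqrt(lam1 / max(lam2, .Machine$double.eps))),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Ellipse fit: orientation %.2f deg, axis ratio %.2f, centroid (%.1f, %.1f)\n",
              x$orientation, x$axis_ratio, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Femur-tibia joint angle from a tibia orientation
#'
#' Converts the tibia's image-axis orientation into the joint angle, given
#' the femur axis orientation (a required calibration input: the image-frame
#' direction the femur points, same angular convention) and the hinge side.
#' The ellipse axis is 180-degree ambiguous; a physical tibia flexes to one
#' known side of the femur, so `hinge_sign` resolves the ambiguity: with the
#' image offset `a = (orientation - femur_axis_angle) mod 180`, the joint
#' angle is `180 - a` for `hinge_sign = +1` and `a` for `hinge_sign = -1`.
#'
#' @param fit an [ellipse_fit()] (or a bare orientation in degrees).
#' @param femur_axis_angle femur axis orientation (degrees).
#' @param hinge_sign +1 or -1, the side toward which the joint flexes.
#' @return Joint angle in degrees, `[0, 180]`.
#' @export
angle_from_orientation <- function(fit, femur_axis_angle, hinge_sign = 1) {
  o <- if (inherits(fit, "ellipse_fit")) fit$orientation else as.numeric(fit)
  check_scalar(o, "orientation")
  check_scalar(femur_axis_angle, "femur_axis_angle")
  if (hinge_sign != 1 && hinge_sign != -1)
    stop_invalid("hinge_sign must be +1 or -1")
  a <- (o - femur_axis_angle) %% 180
  if (hinge_sign == 1) 180 - a else a
}

#' Track the joint angle through a leg video
#'
#' Runs [binarize_pin()], [ellipse_orientation()] and
#' [angle_from_orientation()] on every frame.
#'
#' @param movie an [imaging_movie()] leg video.
#' @param femur_axis_angle femur axis orientation (degrees).
#' @param hinge_sign +1 or -1.
#' @param threshold binarization threshold or `NULL` (per-frame midpoint).
#' @param dark_pin logical contrast polarity flag.
#' @return An [angle_trace()] on the video timebase.
#' @export
track_leg_video <- function(movie, femur_axis_angle, hinge_sign = 1,
                            threshold = NULL, dark_pin = TRUE) {
  stopifnot(inherits(movie, "imaging_movie"))
  nt <- dim(movie$frames)[1]
  angles <- numeric(nt)
  for (t in seq_len(nt)) {
    mask <- binarize_pin(movie$frames[t, , ], threshold, dark_pin)
    fit <- ellipse_orientation(mask)
    angles[t] <- angle_from_orientation(fit, femur_axis_angle, hinge_sign)
  }
  angle_trace(frame_times(movie), pmin(pmax(angles, 0), 180),
              source_rate = 1 / movie$frame_interval,
              metadata = list(femur_axis_angle = femur_axis_angle,
                              hinge_sign = hinge_sign))
}

#' Resample an angle trace onto an imaging timebase
#'
#' Linearly interpolates the angle at each imaging frame time; frame times
#' outside the trace span are clamped to the nearest endpoint and the
#' clamping is recorded in the output metadata.
#'
#' @param angle an [angle_trace()].
#' @param frame_times numeric vector of imaging frame times (s).
#' @return An [angle_trace()] on the imaging timebase.
#' @export
resample_to_frames <- function(angle, frame_times) {
  stopifnot(inherits(angle, "angle_trace"))
  if (length(frame_times) == 0) stop_data("empty frame_times")
  if (any(diff(frame_times) <= 0))
    stop_invalid("frame_times must be strictly increasing")
  clamped <- frame_times < min(angle$times) | frame_times > max(angle$times)
  out <- stats::approx(angle$times, angle$angles, xout = frame_times,
                       rule = 2)$y
  md <- angle$metadata
  md$resampled_from_rate <- angle$source_rate
  md$n_clamped <- sum(clamped)
  angle_trace(frame_times, out,
              source_rate = 1 / stats::median(diff(frame_times)),
              metadata = md)
}
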