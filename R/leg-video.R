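#' Scene parameters for synthetic leg-tracking videos
#'
#' Describes a high-speed video scene of a dark pin (glued to the tibia)
#' rotating about the femur-tibia joint on a bright, IR-illuminated
#' background. Angles use a right-handed image convention: degrees measured
#' from the +column axis, increasing toward decreasing row. The tibia ray is
#' rendered at `femur_axis_angle + hinge_sign * (180 - joint_angle)`, so a
#' fully extended joint (180 deg) lies along the femur axis.
#'
#' @param image_height,image_width frame size (pixels).
#' @param pin_length,pin_width pin dimensions (pixels).
#' @param joint_center (row, col) of the femur-tibia joint, 1-based pixels.
#' @param femur_axis_angle orientation of the femur axis (degrees, image
#'   convention above).
#' @param hinge_sign +1 or -1: the side toward which flexion rotates the
#'   tibia; breaks the 180-degree axis ambiguity during tracking.
#' @param angle_trajectory numeric vector of femur-tibia joint angles
#'   (degrees, one per frame) in `[0, 180]`. Physical preparations rarely
#'   flex below ~18 degrees, but the generator accepts the full range.
#' @param camera_rate video frame rate (frames/s).
#' @param background_level,pin_level image intensities of background and
#'   pin (arbitrary units; background must exceed pin).
#' @param noise_sd per-pixel Gaussian noise SD, >= 0.
#' @param seed integer seed.
#' @return An object of class `leg_scene_params`.
#' @export
leg_scene_params <- function(image_height = 160, image_width = 160,
                             pin_length = 60, pin_width = 6,
                             joint_center = c(80, 80),
                             femur_axis_angle = 0, hinge_sign = 1,
                             angle_trajectory = rep(90, 10),
                             camera_rate = 200,
                             background_level = 1, pin_level = 0.1,
                             noise_sd = 0, seed = 1L) {
  check_scalar(pin_length, "pin_length", positive = TRUE)
  check_scalar(pin_width, "pin_width", positive = TRUE)
  check_scalar(camera_rate, "camera_rate", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (!is.numeric(angle_trajectory) || length(angle_trajectory) < 1L)
    stop_invalid("angle_trajectory must be a nonempty numeric vector")
  if (any(angle_trajectory < 0 | angle_trajectory > 180))
    stop_invalid("angle_trajectory must lie within [0, 180] degrees")
  if (hinge_sign != 1 && hinge_sign != -1)
    stop_invalid("hinge_sign must be +1 or -1")
  if (background_level <= pin_level)
    stop_invalid("background_level must exceed pin_level (dark pin, bright background)")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 pin_length = pin_length, pin_width = pin_width,
                 joint_center = joint_center,
                 femur_axis_angle = femur_axis_angle,
                 hinge_sign = hinge_sign,
                 angle_trajectory = as.numeric(angle_trajectory),
                 camera_rate = camera_rate,
                 background_level = background_level, pin_level = pin_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "leg_scene_params")
}

# Image-space tibia orientation (degrees) for a joint angle under the
# scene's convention.
tibia_image_angle <- function(scene, joint_angle) {
  scene$femur_axis_angle + scene$hinge_sign * (180 - joint_angle)
}

# Fractional pixel coverage of the pin rectangle, by supersampling each
# pixel `ss` x `ss`. The rectangle extends from the joint center `length`
# pixels along `theta_deg`, `width` wide.
render_pin_coverage <- function(h, w, center, theta_deg, length, width, ss = 4) {
  th <- theta_deg * pi / 180
  dir <- c(cos(th), sin(th))     # (x, y) with y = -row
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  sub <- expand.grid(dr = off, dc = off)
  cov <- matrix(0, h, w)
  px_r <- rep(seq_len(h), times = w)
  px_c <- rep(seq_len(w), each = h)
  for (i in seq_len(nrow(sub))) {
    x <- (px_c + sub$dc[i]) - center[2]
    y <- -((px_r + sub$dr[i]) - center[1])
    u <- x * dir[1] + y * dir[2]
    v <- -x * dir[2] + y * dir[1]
    inside <- u >= 0 & u <= length & abs(v) <= width / 2
    cov <- cov + matrix(as.numeric(inside), h, w)
  }
  cov / nrow(sub)
}

#' Generate a synthetic leg-tracking video with ground-truth angles
#'
#' Renders one frame per trajectory sample: a dark pin rotated about the
#' joint center to the frame's femur-tibia angle on a bright background,
#' with optional seeded Gaussian noise. Edge pixels get partial (supersampled)
#' coverage, emulating optical blur at the pin boundary.
#'
#' @param scene a [leg_scene_params()].
#' @param ss supersampling factor per pixel edge for coverage rendering.
#' @return A list with `movie` ([imaging_movie()]) and `truth`
#'   ([angle_trace()] of the rendered joint angles on the camera timebase).
#' @export
gen_leg_video <- function(scene, ss = 4) {
  stopifnot(inherits(scene, "leg_scene_params"))
  h <- scene$image_height; w <- scene$image_width
  nt <- length(scene$angle_trajectory)
  frames <- array(0, dim = c(nt, h, w))
  for (t in seq_len(nt)) {
    theta <- tibia_image_angle(scene, scene$angle_trajectory[t])
    th <- theta * pi / 180
    tip <- c(scene$joint_center[1] - sin(th) * scene$pin_length,
             scene$joint_center[2] + cos(th) * scene$pin_length)
    half <- scene$pin_width / 2 + 1
    if (tip[1] < half || tip[1] > h - half + 1 || tip[2] < half || tip[2] > w - half + 1 ||
        scene$joint_center[1] < half || scene$joint_center[1] > h - half + 1 ||
        scene$joint_center[2] < half || scene$joint_center[2] > w - half + 1)
      stop_data("pin exits the frame at frame ", t, " (joint angle ",
                fmt_num(scene$angle_trajectory[t]), " deg)",
                class = "fcmap_render_error")
    cov <- render_pin_coverage(h, w, scene$joint_center, theta,
                               scene$pin_length, scene$pin_width, ss = ss)
    frames[t, , ] <- scene$background_level -
      (scene$background_level - scene$pin_level) * cov
  }
  if (scene$noise_sd > 0) {
    frames <- with_seed(scene$seed, {
      pmax(frames + array(stats::rnorm(length(frames), sd = scene$noise_sd),
                          dim = dim(frames)), 0)
    })
  }
  movie <- imaging_movie(frames, frame_interval = 1 / scene$camera_rate,
                         metadata = list(kind = "synthetic_leg_video",
                                         seed = scene$seed,
                                         femur_axis_angle = scene$femur_axis_angle,
                                         hinge_sign = scene$hinge_sign))
  truth <- angle_trace(times = (seq_len(nt) - 1) / scene$camera_rate,
                       angles = scene$angle_trajectory,
                       source_rate = scene$camera_rate)
  list(movie = movie, truth = truth)
}
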