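VNC_NEUROMERES <- c("T1L", "T1R", "T2L", "T2R", "T3L", "T3R")

# mean over flies of within-fly means; the single aggregation convention
# used for all group summaries.
two_stage_mean <- function(fly, value) {
  mean(tapply(value, factor(fly, levels = unique(fly)), mean))
}

check_trials <- function(trials) {
  need <- c("fly_id", "pre_label", "post_label", "intensity", "f_peak")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop_invalid("trials must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  if (nrow(trials) == 0) stop_data("no trials supplied")
  if (any(!is.finite(trials$intensity)) || any(trials$intensity <= 0))
    stop_invalid("trial intensities must be finite and > 0")
  trials
}

#' Intensity-response curve for one pre/post pair
#'
#' For each stimulation intensity, averages peak responses within each fly
#' and then across flies; intensities are reported in ascending order.
#'
#' @param trials data.frame with columns `fly_id`, `pre_label`,
#'   `post_label`, `intensity`, `f_peak`, all for a single pre/post pair.
#' @return An object of class `intensity_curve`: `intensities` (ascending),
#'   `mean_f_peak`, `per_fly` (fly x intensity matrix of within-fly means,
#'   `NA` where a fly was not tested), `n_flies` per intensity.
#' @export
intensity_response_curve <- function(trials) {
  trials <- check_trials(trials)
  if (length(unique(paste(trials$pre_label, trials$post_label))) > 1L)
    stop_invalid("trials must belong to a single pre/post pair")
  ints <- sort(unique(trials$intensity))
  flies <- unique(trials$fly_id)
  per_fly <- matrix(NA_real_, length(flies), length(ints),
                    dimnames = list(as.character(flies), as.character(ints)))
  for (f in seq_along(flies)) {
    for (q in seq_along(ints)) {
      sel <- trials$fly_id == flies[f] & trials$intensity == ints[q]
      if (any(sel)) per_fly[f, q] <- mean(trials$f_peak[sel])
    }
  }
  structure(list(intensities = ints,
                 mean_f_peak = apply(per_fly, 2, mean, na.rm = TRUE),
                 per_fly = per_fly,
                 n_flies = apply(per_fly, 2, function(v) sum(!is.na(v)))),
            class = "intensity_curve")
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat("Intensity-response curve:\n")
  print(data.frame(intensity = x$intensities,
                   mean_f_peak = unname(x$mean_f_peak),
                   n_flies = unname(x$n_flies)))
  invisible(x)
}

#' @export
plot.intensity_curve <- function(x, ...) {
  graphics::plot(x$intensities, x$mean_f_peak, type = "b", log = "x",
                 xlab = expression("stimulus intensity (mW/mm"^2 * ")"),
                 ylab = expression("peak " * Delta * F / F), ...)
  invisible(x)
}

#' Select the protocol intensity nearest a plateau target
#'
#' Calcium responses typically plateau near 0.3 mW/mm^2, so group analyses
#' use the protocol intensity closest to that target (0.28 mW/mm^2 for the
#' standard six-pulse protocol). Ties go to the lower intensity.
#'
#' @param curve an [intensity_response_curve()] result, or a numeric vector
#'   of protocol intensities.
#' @param target plateau target intensity (mW/mm^2).
#' @return The chosen intensity (mW/mm^2).
#' @export
select_plateau_intensity <- function(curve, target = 0.3) {
  ints <- if (inherits(curve, "intensity_curve")) curve$intensities else as.numeric(curve)
  if (length(ints) == 0) stop_data("empty intensity curve")
  ints <- sort(ints)
  d <- abs(ints - target)
  ints[which.min(d)]  # sorted ascending, so which.min ties to the lower one
}

new_connectivity_matrix <- function(values, n_flies, intensity_used, kind) {
  structure(list(values = values, n_flies = n_flies,
                 intensity_used = intensity_used, kind = kind),
            class = "connectivity_matrix")
}

#' Build a connectivity matrix from trial records
#'
#' Cell (pre, post) holds the mean over flies of within-fly mean peak
#' responses at a single stimulation intensity. Pairs never tested are
#' `NA` (missing), never zero.
#'
#' @param trials data.frame of trial records (`fly_id`, `pre_label`,
#'   `post_label`, `intensity`, `f_peak`), all at one intensity.
#' @param intensity the stimulation intensity the matrix is built at
#'   (mW/mm^2); supplying trials at any other intensity is an error.
#' @param pre_levels,post_levels optional row/column label order; default
#'   sorted unique labels observed.
#' @return An object of class `connectivity_matrix` with `values` and
#'   `n_flies` matrices and `intensity_used`.
#' @export
build_matrix <- function(trials, intensity, pre_levels = NULL, post_levels = NULL) {
  trials <- check_trials(trials)
  check_scalar(intensity, "intensity", positive = TRUE)
  if (any(trials$intensity != intensity))
    stop_data("trials contain intensities other than ", intensity,
              " mW/mm^2; filter before building the matrix")
  if (is.null(pre_levels)) pre_levels <- sort(unique(trials$pre_label))
  if (is.null(post_levels)) post_levels <- sort(unique(trials$post_label))
  if (!all(trials$pre_label %in% pre_levels) ||
      !all(trials$post_label %in% post_levels))
    stop_data("trial labels outside the declared vocabularies")
  vals <- matrix(NA_real_, length(pre_levels), length(post_levels),
                 dimnames = list(pre_levels, post_levels))
  nfly <- matrix(0L, length(pre_levels), length(post_levels),
                 dimnames = list(pre_levels, post_levels))
  for (i in seq_along(pre_levels)) {
    for (j in seq_along(post_levels)) {
      sel <- trials$pre_label == pre_levels[i] & trials$post_label == post_levels[j]
      if (any(sel)) {
        sub <- trials[sel, ]
        vals[i, j] <- two_stage_mean(sub$fly_id, sub$f_peak)
        nfly[i, j] <- length(unique(sub$fly_id))
      }
    }
  }
  new_connectivity_matrix(vals, nfly, intensity, kind = "pre_by_post")
}

#' Build the 6-leg x 6-neuromere segment map
#'
#' Same two-stage averaging as [build_matrix()], with rows fixed to the
#' stimulated leg and columns to the recorded neuromere, both over the
#' six-neuromere vocabulary T1L, T1R, T2L, T2R, T3L, T3R.
#'
#' @param trials data.frame of trial records whose `pre_label` (stimulated
#'   leg) and `post_label` (recorded neuromere) are neuromere labels.
#' @param intensity stimulation intensity (mW/mm^2).
#' @return A 6 x 6 `connectivity_matrix`.
#' @export
build_segment_map <- function(trials, intensity) {
  trials <- check_trials(trials)
  bad <- setdiff(unique(c(trials$pre_label, trials$post_label)), VNC_NEUROMERES)
  if (length(bad))
    stop_data("unknown neuromere label(s): ", paste(bad, collapse = ", "))
  m <- build_matrix(trials, intensity,
                    pre_levels = VNC_NEUROMERES, post_levels = VNC_NEUROMERES)
  m$kind <- "leg_by_neuromere"
  m
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix (%s) at %g mW/mm^2:\n", x$kind, x$intensity_used))
  print(round(x$values, 4))
  cat("flies per cell:\n")
  print(x$n_flies)
  invisible(x)
}

#' @export
plot.connectivity_matrix <- function(x, ...) {
  v <- x$values
  z <- t(v[nrow(v):1, , drop = FALSE])
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", useRaster = TRUE, ...)
  graphics::axis(1, at = seq_len(ncol(v)), labels = colnames(v), las = 2)
  graphics::axis(2, at = seq_len(nrow(v)), labels = rev(rownames(v)), las = 1)
  graphics::box()
  invisible(x)
}

#' @export
summary.connectivity_matrix <- function(object, ...) {
  v <- object$values
  cat(sprintf("Connectivity matrix %d x %d at %g mW/mm^2\n",
              nrow(v), ncol(v), object$intensity_used))
  cat(sprintf("  measured cells: %d of %d; value range %s to %s\n",
              sum(!is.na(v)), length(v),
              fmt_num(min(v, na.rm = TRUE)), fmt_num(max(v, na.rm = TRUE))))
  invisible(object)
}
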