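#' Response kinetics container
#'
#' Per-trace response summary: peak dF/F in the stimulation window and when
#' it occurs, time to half-peak on the rise (relative to stimulus onset),
#' half-decay time (relative to the peak; `NA` when the trace never decays
#' to half within the trial), the offset-time dF/F, and the adaptation index
#' `1 - f_offset / f_peak`.
#'
#' @param f_peak peak dF/F in the stimulation window.
#' @param t_peak time of the peak (s, absolute trace time).
#' @param t50_rise time to 50% of peak after onset (s), or `NA`.
#' @param t50_decay half-decay time after the peak (s), or `NA`.
#' @param f_offset dF/F at the offset sampling time, or `NA`.
#' @param adaptation_index `1 - f_offset / f_peak`, or `NA`.
#' @return An object of class `response_kinetics`.
#' @export
response_kinetics <- function(f_peak = NA_real_, t_peak = NA_real_,
                              t50_rise = NA_real_, t50_decay = NA_real_,
                              f_offset = NA_real_, adaptation_index = NA_real_) {
  structure(list(f_peak = f_peak, t_peak = t_peak, t50_rise = t50_rise,
                 t50_decay = t50_decay, f_offset = f_offset,
                 adaptation_index = adaptation_index),
            class = "response_kinetics")
}

#' @export
print.response_kinetics <- function(x, ...) {
  cat("Response kinetics:\n")
  cat(sprintf("  f_peak      %s at t = %s s\n", fmt_num(x$f_peak), fmt_num(x$t_peak)))
  cat(sprintf("  t50 rise    %s s after onset\n", fmt_num(x$t50_rise)))
  cat(sprintf("  t50 decay   %s s after peak\n",
              if (is.na(x$t50_decay)) "not reached" else fmt_num(x$t50_decay)))
  if (!is.na(x$f_offset))
    cat(sprintf("  f_offset    %s; adaptation index %s\n",
                fmt_num(x$f_offset), fmt_num(x$adaptation_index)))
  invisible(x)
}

#' Peak response within a stimulation window
#'
#' Maximum dF/F over frames with `onset <= t <= onset + duration`; the
#' earliest frame wins ties.
#'
#' @param trace a [dff_trace()].
#' @param stim_onset stimulus onset (s).
#' @param stim_duration stimulation window length (s).
#' @return A [response_kinetics()] with `f_peak` and `t_peak` filled.
#' @export
peak_response <- function(trace, stim_onset, stim_duration) {
  stopifnot(inherits(trace, "dff_trace"))
  check_scalar(stim_onset, "stim_onset")
  check_scalar(stim_duration, "stim_duration", positive = TRUE)
  inside <- trace$times >= stim_onset & trace$times <= stim_onset + stim_duration
  if (!any(inside))
    stop_data("stimulation window [", stim_onset, ", ", stim_onset + stim_duration,
              "] s does not overlap the trace")
  v <- trace$values[inside]
  tt <- trace$times[inside]
  i <- which.max(v)  # earliest tie
  response_kinetics(f_peak = v[i], t_peak = tt[i])
}

# First crossing of `thr` in direction `dir` (+1 up, -1 down) among samples
# (tt, vv), linearly interpolated; NA if none.
first_crossing <- function(tt, vv, thr, dir) {
  if (length(vv) == 0) return(NA_real_)
  if (dir > 0 && vv[1] >= thr) return(tt[1])
  if (dir < 0 && vv[1] <= thr) return(tt[1])
  for (i in seq_len(length(vv) - 1)) {
    a <- vv[i]; b <- vv[i + 1]
    hit <- if (dir > 0) a < thr && b >= thr else a > thr && b <= thr
    if (hit) {
      if (a == b) return(tt[i + 1])
      return(tt[i] + (thr - a) / (b - a) * (tt[i + 1] - tt[i]))
    }
  }
  NA_real_
}

#' Rise and half-decay times of a response
#'
#' `t50_rise` is the first upward crossing of half the peak at or after the
#' stimulus onset, reported relative to onset; `t50_decay` is the first
#' downward crossing of half the peak after the peak time, relative to the
#' peak. Crossings are linearly interpolated between frames so the metrics
#' do not quantize to the frame grid; a trace that never falls to half-peak
#' before the trial ends gets `t50_decay = NA`.
#'
#' @param trace a [dff_trace()].
#' @param stim_onset stimulus onset (s).
#' @param kinetics a [response_kinetics()] with `f_peak`/`t_peak` filled
#'   (from [peak_response()]).
#' @return The [response_kinetics()] with `t50_rise` and `t50_decay` filled.
#' @export
rise_decay_times <- function(trace, stim_onset, kinetics) {
  stopifnot(inherits(trace, "dff_trace"), inherits(kinetics, "response_kinetics"))
  if (is.na(kinetics$f_peak) || kinetics$f_peak <= 0)
    stop_data("kinetics undefined for f_peak <= 0 (non-excitatory response)",
              class = "fcmap_undefined_kinetics")
  thr <- kinetics$f_peak / 2
  rise_idx <- trace$times >= stim_onset & trace$times <= kinetics$t_peak
  t_rise <- first_crossing(trace$times[rise_idx], trace$values[rise_idx], thr, +1)
  kinetics$t50_rise <- if (is.na(t_rise)) NA_real_ else t_rise - stim_onset
  dec_idx <- trace$times >= kinetics$t_peak
  t_dec <- first_crossing(trace$times[dec_idx], trace$values[dec_idx], thr, -1)
  # the peak itself sits above thr, so a returned crossing is genuine decay
  kinetics$t50_decay <- if (is.na(t_dec)) NA_real_ else t_dec - kinetics$t_peak
  kinetics
}

#' Adaptation index of a sustained response
#'
#' Quantifies decay of a calcium response during sustained stimulation as
#' `1 - f_offset / f_peak`, where `f_peak` is the peak dF/F in the
#' stimulation window and `f_offset` is the dF/F at the frame nearest
#' `stim_onset + offset_lag` (default 19 s, where stimulation offset
#' typically falls for the relevant cell types). An index of 1 means full
#' decay back to baseline, 0 means no adaptation, and negative values mean
#' the signal grew over time.
#'
#' @param trace a [dff_trace()].
#' @param stim_onset stimulus onset (s).
#' @param stim_duration window used for the peak search (s); defaults to
#'   `offset_lag`.
#' @param offset_lag lag after onset at which `f_offset` is sampled (s).
#' @return A [response_kinetics()] with `f_peak`, `t_peak`, `f_offset` and
#'   `adaptation_index` filled.
#' @export
adaptation_index <- function(trace, stim_onset, stim_duration = offset_lag,
                             offset_lag = 19) {
  stopifnot(inherits(trace, "dff_trace"))
  check_scalar(offset_lag, "offset_lag", positive = TRUE)
  t_off <- stim_onset + offset_lag
  if (max(trace$times) < t_off)
    stop_data("trace ends at ", fmt_num(max(trace$times)),
              " s, before the offset sampling time ", fmt_num(t_off), " s")
  kin <- peak_response(trace, stim_onset, stim_duration)
  if (kin$f_peak <= 0)
    stop_data("adaptation index undefined for f_peak <= 0",
              class = "fcmap_undefined_index")
  i <- which.min(abs(trace$times - t_off))  # nearest frame, no interpolation
  kin$f_offset <- trace$values[i]
  kin$adaptation_index <- 1 - kin$f_offset / kin$f_peak
  kin
}

#' Cap a per-pixel response map for display
#'
#' Pixels strictly above the cap (default 3.0, i.e. 300% dF/F) are flagged
#' as outliers and rendered white; values at or below the cap pass through
#' untouched.
#'
#' @param map numeric matrix of per-pixel peak dF/F, all finite.
#' @param cap display cap (dF/F).
#' @return A list of class `capped_map`: `display` (matrix with capped
#'   pixels set to `NA`), `capped` (logical mask), `values` (the input),
#'   `cap`.
#' @export
cap_pixel_map <- function(map, cap = 3.0) {
  map <- as.matrix(map)
  if (any(!is.finite(map))) stop_invalid("map must be finite")
  check_scalar(cap, "cap")
  capped <- map > cap
  display <- map
  display[capped] <- NA_real_
  structure(list(display = display, capped = capped, values = map, cap = cap),
            class = "capped_map")
}

#' @export
plot.capped_map <- function(x, ...) {
  z <- t(x$display[nrow(x$display):1, , drop = FALSE])
  graphics::image(z, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

#' Vibration tuning curve with two-stage averaging
#'
#' Summarizes per-trial responses to tibia vibration into a frequency tuning
#' curve: responses are first averaged over repetitions within each fly, and
#' the curve is the unweighted mean of those per-fly values across flies.
#'
#' @param responses data.frame with columns `fly`, `frequency`, `response`
#'   (one row per repetition).
#' @return An object of class `tuning_curve`: `frequencies` (increasing),
#'   `mean_response`, `per_fly` (fly x frequency matrix of within-fly
#'   means), `n_flies`.
#' @export
vibration_tuning <- function(responses) {
  need <- c("fly", "frequency", "response")
  if (!is.data.frame(responses) || !all(need %in% names(responses)))
    stop_invalid("responses must be a data.frame with columns fly, frequency, response")
  flies <- unique(responses$fly)
  freqs <- sort(unique(responses$frequency))
  per_fly <- matrix(NA_real_, length(flies), length(freqs),
                    dimnames = list(as.character(flies), as.character(freqs)))
  for (f in seq_along(flies)) {
    for (q in seq_along(freqs)) {
      sel <- responses$fly == flies[f] & responses$frequency == freqs[q]
      if (!any(sel))
        stop_data("fly '", flies[f], "' has no repetitions at frequency ",
                  freqs[q], " Hz")
      per_fly[f, q] <- mean(responses$response[sel])
    }
  }
  structure(list(frequencies = freqs,
                 mean_response = colMeans(per_fly),
                 per_fly = per_fly, n_flies = length(flies)),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve: %d frequencies, %d flies\n",
              length(x$frequencies), x$n_flies))
  print(data.frame(frequency = x$frequencies, mean_dff = unname(x$mean_response)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::matplot(x$frequencies, t(x$per_fly), type = "l", lty = 1,
                    col = "grey70", xlab = "vibration frequency (Hz)",
                    ylab = expression(Delta * F / F), ...)
  graphics::lines(x$frequencies, x$mean_response, lwd = 2)
  invisible(x)
}
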