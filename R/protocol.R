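#' Build an optogenetic pulse-train stimulus protocol
#'
#' Describes a train of light pulses of escalating intensity, as used for
#' optogenetic functional connectivity mapping: pulse `k` (0-based) starts at
#' `k * (pulse_duration + inter_pulse)` seconds and carries its own intensity.
#' Within each pulse the light is square-wave modulated (50% duty cycle), so
#' the time-averaged drive during a pulse is `duty * intensity`. The default
#' arguments reproduce the standard mapping protocol: six 5 s pulses at
#' 0.02, 0.04, 0.12, 0.28, 0.37 and 0.68 mW/mm^2 with a 30 s inter-pulse
#' interval and 50 Hz modulation.
#'
#' @param intensities numeric vector of pulse intensities (mW/mm^2),
#'   strictly positive, one per pulse in presentation order.
#' @param pulse_duration pulse length in seconds.
#' @param inter_pulse interval between pulse offset and the next onset (s).
#' @param modulation_hz frequency of the within-pulse square-wave
#'   modulation (Hz).
#' @param duty duty cycle of the modulation in (0, 1].
#' @return An object of class `stim_protocol`: a list with `onsets`,
#'   `durations`, `intensities` (all per pulse), `inter_pulse`,
#'   `modulation_hz`, `duty`, and `total_span` (end of the last pulse, s).
#' @examples
#' p <- gen_stimulus_protocol()
#' p$onsets     # 0, 35, 70, ...
#' @export
gen_stimulus_protocol <- function(intensities = c(0.02, 0.04, 0.12, 0.28, 0.37, 0.68),
                                  pulse_duration = 5,
                                  inter_pulse = 30,
                                  modulation_hz = 50,
                                  duty = 0.5) {
  if (length(intensities) < 1L || !is.numeric(intensities))
    stop_invalid("intensities must be a nonempty numeric vector")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop_invalid("intensities must be finite and strictly positive")
  check_scalar(pulse_duration, "pulse_duration", positive = TRUE)
  check_scalar(inter_pulse, "inter_pulse", nonneg = TRUE)
  check_scalar(modulation_hz, "modulation_hz", positive = TRUE)
  check_scalar(duty, "duty", positive = TRUE)
  if (duty > 1) stop_invalid("duty must be in (0, 1]")

  n <- length(intensities)
  onsets <- (seq_len(n) - 1) * (pulse_duration + inter_pulse)
  structure(list(
    onsets = onsets,
    durations = rep(pulse_duration, n),
    intensities = as.numeric(intensities),
    inter_pulse = inter_pulse,
    modulation_hz = modulation_hz,
    duty = duty,
    total_span = onsets[n] + pulse_duration
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d pulse(s), %g s each, %g s inter-pulse\n",
              length(x$onsets), x$durations[1], x$inter_pulse))
  cat(sprintf("  modulation: %g Hz square wave, duty %g\n", x$modulation_hz, x$duty))
  cat("  intensities (mW/mm^2):", paste(fmt_num(x$intensities), collapse = ", "), "\n")
  cat(sprintf("  total span: %g s\n", x$total_span))
  invisible(x)
}

# Time-averaged light drive (duty-scaled intensity, mW/mm^2) at times `t`.
# Frames integrate the fast square-wave modulation, which imaging frame
# rates cannot resolve, so the envelope is represented by its duty cycle.
protocol_drive <- function(protocol, t) {
  drive <- numeric(length(t))
  for (k in seq_along(protocol$onsets)) {
    on <- protocol$onsets[k]
    inside <- t >= on & t < on + protocol$durations[k]
    drive[inside] <- protocol$duty * protocol$intensities[k]
  }
  drive
}
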