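#' Generate sinusoidal tibia-vibration stimulus epochs
#'
#' Builds the piezo command waveforms for tibia vibration: for each requested
#' frequency, `n_reps` sine epochs of `epoch_duration` seconds separated by
#' `isi` seconds, sampled at `sample_rate`. The defaults reproduce the
#' standard presentation: 4 s of vibration, 2 repetitions, 8 s inter-stimulus
#' interval, 10 kHz command sampling. Within a frequency, epoch `j` (0-based)
#' starts at `j * (epoch_duration + isi)` s; each epoch's waveform starts at
#' phase 0 (`sin(0) = 0`).
#'
#' @param frequencies numeric vector of vibration frequencies (Hz), > 0.
#' @param epoch_duration epoch length (s).
#' @param n_reps repetitions per frequency.
#' @param isi inter-stimulus interval between epochs (s).
#' @param sample_rate command sampling rate (Hz); must exceed twice the
#'   highest requested frequency.
#' @param amplitude peak waveform amplitude (arbitrary command units).
#' @return An object of class `vibration_stimulus`: a list with `epochs`
#'   (data.frame `frequency`, `rep`, `onset_s`, `n_samples`), `waveforms`
#'   (list of numeric vectors, one per epoch, in `epochs` row order), and
#'   the echoed parameters.
#' @export
gen_vibration_epochs <- function(frequencies, epoch_duration = 4, n_reps = 2,
                                 isi = 8, sample_rate = 10000, amplitude = 1) {
  if (length(frequencies) < 1L || !is.numeric(frequencies))
    stop_invalid("frequencies must be a nonempty numeric vector")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop_invalid("frequencies must be finite and strictly positive")
  check_scalar(epoch_duration, "epoch_duration", positive = TRUE)
  check_scalar(n_reps, "n_reps", positive = TRUE)
  check_scalar(isi, "isi", nonneg = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate <= 2 * max(frequencies))
    stop_invalid("sample_rate must exceed twice the highest frequency (Nyquist)")

  n_samples <- round(epoch_duration * sample_rate)
  tt <- (seq_len(n_samples) - 1) / sample_rate
  epochs <- expand.grid(rep = seq_len(n_reps) - 1L, frequency = frequencies)
  epochs <- epochs[, c("frequency", "rep")]
  epochs$onset_s <- epochs$rep * (epoch_duration + isi)
  epochs$n_samples <- n_samples
  waveforms <- lapply(seq_len(nrow(epochs)), function(i) {
    amplitude * sin(2 * pi * epochs$frequency[i] * tt)
  })
  structure(list(epochs = epochs, waveforms = waveforms,
                 epoch_duration = epoch_duration, isi = isi,
                 sample_rate = sample_rate, amplitude = amplitude),
            class = "vibration_stimulus")
}

#' @export
print.vibration_stimulus <- function(x, ...) {
  cat(sprintf("Vibration stimulus: %d frequency(ies) x %d rep(s), %g s epochs, %g s ISI, %g Hz sampling\n",
              length(unique(x$epochs$frequency)), max(x$epochs$rep) + 1,
              x$epoch_duration, x$isi, x$sample_rate))
  cat("  frequencies (Hz):", paste(unique(x$epochs$frequency), collapse = ", "), "\n")
  invisible(x)
}
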