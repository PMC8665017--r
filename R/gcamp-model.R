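#' Parametric GCaMP-like response model
#'
#' A minimal phenomenological model of a slow calcium indicator's response
#' to optogenetic drive, used by the synthetic-data generator. The light
#' drive (duty-scaled intensity, see [gen_stimulus_protocol()]) is convolved
#' with a difference-of-exponentials kernel
#' `k(t) = (exp(-t/decay_tau) - exp(-t/rise_tau)) / (decay_tau - rise_tau)`
#' (unit integral, so a sustained drive converges to its own amplitude),
#' then passed through a saturating Michaelis-Menten amplitude map
#' `A(x) = amp_max * x / (x + half_sat)` giving steady-state dF/F as a
#' nondecreasing, bounded function of intensity. Optionally, a multiplicative
#' adaptation factor decays from 1 toward `adaptation_floor` with time
#' constant `adaptation_tau` from each pulse onset.
#'
#' The kinetic constants are free parameters of the generator (not fitted to
#' any recording); defaults give GCaMP6s-like sluggish transients.
#'
#' @param rise_tau rise time constant (s), > 0.
#' @param decay_tau decay time constant (s), > 0 and different from
#'   `rise_tau`.
#' @param amp_max maximum steady-state dF/F of the amplitude map.
#' @param half_sat drive (mW/mm^2) at which the amplitude map reaches half
#'   of `amp_max`.
#' @param adaptation_tau adaptation time constant (s), or `NULL` to disable
#'   adaptation (the default).
#' @param adaptation_floor asymptotic plateau of the adaptation factor,
#'   in `[0, 1]`.
#' @return An object of class `gcamp_model`.
#' @examples
#' m <- gcamp_model()
#' steady_state_dff(m, 0.28, duty = 0.5)
#' @export
gcamp_model <- function(rise_tau = 0.4, decay_tau = 1.8,
                        amp_max = 2.0, half_sat = 0.05,
                        adaptation_tau = NULL, adaptation_floor = 0.1) {
  check_scalar(rise_tau, "rise_tau", positive = TRUE)
  check_scalar(decay_tau, "decay_tau", positive = TRUE)
  if (rise_tau == decay_tau)
    stop_invalid("rise_tau and decay_tau must differ (kernel is a difference of exponentials)")
  check_scalar(amp_max, "amp_max", positive = TRUE)
  check_scalar(half_sat, "half_sat", positive = TRUE)
  if (!is.null(adaptation_tau)) check_scalar(adaptation_tau, "adaptation_tau", positive = TRUE)
  check_scalar(adaptation_floor, "adaptation_floor", nonneg = TRUE)
  if (adaptation_floor > 1) stop_invalid("adaptation_floor must be in [0, 1]")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amp_max = amp_max, half_sat = half_sat,
                 adaptation_tau = adaptation_tau,
                 adaptation_floor = adaptation_floor),
            class = "gcamp_model")
}

#' @export
print.gcamp_model <- function(x, ...) {
  cat(sprintf("GCaMP-like response model: rise tau %g s, decay tau %g s\n",
              x$rise_tau, x$decay_tau))
  cat(sprintf("  amplitude map: %g * x / (x + %g)\n", x$amp_max, x$half_sat))
  if (is.null(x$adaptation_tau)) {
    cat("  adaptation: disabled\n")
  } else {
    cat(sprintf("  adaptation: tau %g s toward floor %g\n",
                x$adaptation_tau, x$adaptation_floor))
  }
  invisible(x)
}

#' Steady-state dF/F of the model at a given light intensity
#'
#' Evaluates the saturating amplitude map at the duty-scaled intensity:
#' the dF/F a sustained modulated pulse converges to.
#'
#' @param model a [gcamp_model()].
#' @param intensity light intensity (mW/mm^2), >= 0.
#' @param duty modulation duty cycle in (0, 1]; default 1 (continuous light).
#' @return Steady-state dF/F (dimensionless).
#' @export
steady_state_dff <- function(model, intensity, duty = 1) {
  stopifnot(inherits(model, "gcamp_model"))
  x <- duty * intensity
  model$amp_max * x / (x + model$half_sat)
}

# Integral of the unit-area difference-of-exponentials kernel from 0 to t
# (the step response of the linear stage); 0 for t < 0.
kernel_step <- function(t, rise_tau, decay_tau) {
  s <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  s[pos] <- 1 - (decay_tau * exp(-tp / decay_tau) - rise_tau * exp(-tp / rise_tau)) /
    (decay_tau - rise_tau)
  s
}

#' Noiseless model response to a stimulus protocol
#'
#' Evaluates the model's dF/F response at arbitrary times, analytically
#' (superposition of pulse step responses through the linear kernel stage,
#' then the saturating amplitude map, then the optional adaptation factor).
#'
#' @param model a [gcamp_model()].
#' @param protocol a [gen_stimulus_protocol()] object.
#' @param times numeric vector of times (s).
#' @return Numeric vector of dF/F values, one per time.
#' @export
model_response <- function(model, protocol, times) {
  stopifnot(inherits(model, "gcamp_model"), inherits(protocol, "stim_protocol"))
  s <- numeric(length(times))
  for (k in seq_along(protocol$onsets)) {
    u <- protocol$duty * protocol$intensities[k]
    on <- protocol$onsets[k]
    off <- on + protocol$durations[k]
    s <- s + u * (kernel_step(times - on, model$rise_tau, model$decay_tau) -
                    kernel_step(times - off, model$rise_tau, model$decay_tau))
  }
  r <- model$amp_max * s / (s + model$half_sat)
  if (!is.null(model$adaptation_tau)) {
    # adaptation clock restarts at each pulse onset
    m <- rep(1, length(times))
    for (k in seq_along(protocol$onsets)) {
      on <- protocol$onsets[k]
      upto <- if (k < length(protocol$onsets)) protocol$onsets[k + 1] else Inf
      idx <- times >= on & times < upto
      m[idx] <- model$adaptation_floor + (1 - model$adaptation_floor) *
        exp(-(times[idx] - on) / model$adaptation_tau)
    }
    r <- r * m
  }
  r
}
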