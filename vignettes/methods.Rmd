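---
title: "Methods: from calcium movies to connectivity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium movies to connectivity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmap)
```

`fcmap` quantifies functional connectivity between leg proprioceptor
subtypes and central ventral-nerve-cord neurons from two-photon calcium
imaging during optogenetic stimulation. This vignette documents the models
and procedures, the parameters that matter, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## The stimulation protocol

Mapping experiments use a pulse train of escalating light intensity:
`gen_stimulus_protocol()` defaults to six 5 s pulses at 0.02, 0.04, 0.12,
0.28, 0.37 and 0.68 mW/mm² with a 30 s inter-pulse interval, each pulse
square-wave modulated at 50 Hz with 50% duty cycle. Imaging frame rates
(2.5 frames/s for connectivity mapping, 8.01 Hz during leg movements)
cannot resolve 50 Hz, and a frame integrates the light it spans, so the
modulation is represented analytically by its duty cycle: the effective
drive during a pulse is `duty * intensity`. Because responses saturate near
0.3 mW/mm², group analyses use the protocol intensity closest to that
target (`select_plateau_intensity()`, 0.28 mW/mm² for the default train;
ties go to the lower intensity, the conservative choice).

## The synthetic response model

The generator's indicator model (`gcamp_model()`) has three stages:

1. **Linear kinetics.** The drive is convolved with a unit-area
   difference-of-exponentials kernel,
   $k(t) = \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\tau_d - \tau_r}$.
   Because the kernel integrates to one, a sustained drive converges to its
   own amplitude, which makes steady states easy to reason about. For
   piecewise-constant drives the convolution has a closed form
   (superposed step responses), so ground-truth traces are evaluated
   analytically at frame times rather than by discrete convolution.
2. **Saturation.** The smoothed drive passes through a Michaelis–Menten
   amplitude map $A(x) = A_{max}\, x / (x + K)$, giving a nondecreasing,
   bounded steady-state ΔF/F per intensity. Defaults $A_{max} = 2$,
   $K = 0.05$ mW/mm² put the half-saturation well below the 0.28 mW/mm²
   plateau intensity, reproducing the observed flattening of
   intensity-response curves around 0.3 mW/mm².
3. **Adaptation (optional, off by default).** A multiplicative factor
   decaying from 1 toward `adaptation_floor` with time constant
   `adaptation_tau`, restarted at each pulse onset. It exists to emulate
   slow response decay during sustained stimulation and is only enabled for
   adaptation-focused analyses.

The kinetic constants (defaults $\tau_r = 0.4$ s, $\tau_d = 1.8$ s,
GCaMP6s-like sluggishness) are free parameters of the generator, chosen
once as plausible for a slow indicator; they are not fitted to any
recording, and no analysis result depends on their particular values —
tests compare pipeline output against the same model's closed forms.

Movies paint each ROI's signal `baseline * (1 + g * r(t))` onto a disk
dilated by the smoothing kernel's half-width (2 px), with the planted gain
`g` for the ROI's (pre, post) pair; pixels outside ROIs sit at a dimmer
background (default one tenth of baseline, emulating unlabelled tissue).
The dilation means spatial smoothing leaves ROI-interior pixels exactly
unchanged, so ground-truth recovery tests probe the ΔF/F logic, not edge
artifacts. Noise is independent per pixel per frame, Gaussian with a floor
at zero — adequate for SNR studies at this scale, though it is not a photon
(shot-noise) model, has no optical PSF, and no motion artifacts; passing
tests therefore validate the analysis logic, not robustness to those
real-data features. All randomness flows from explicit seeds through a
save/restore wrapper, so generation is bit-reproducible and never perturbs
the caller's RNG state.

## ΔF/F extraction

`gaussian_smooth()` convolves each frame independently with a normalized
5×5 Gaussian (σ = 3 px) using reflect padding, which preserves constant
images and avoids dark edges. `apply_threshold()` zeroes pixels strictly
below a threshold; the automatic mode maximizes between-class variance
(Otsu) over a 256-bin histogram. The threshold is pooled over the whole
movie by default: computed per frame, the threshold drifts upward during
strong pulses (a third, brighter intensity class appears) and can zero
resting-tissue pixels, corrupting baselines of unresponsive ROIs —
`otsu_scope = "frame"` remains available for stationary scenes. Zeroed
pixels still participate in ROI means, keeping ROI geometry fixed across
frames.

The baseline F₀ is the minimum over all contiguous 10-frame windows of the
window-mean (stride 1; ties go to the earliest window), computed per trial.
For signals reduced below rest by the stimulus, that minimum would chase
the inhibition itself, so the `initial-window` mode uses the first ten
frames instead. A baseline ≤ 0 is refused rather than silently producing
unusable ratios. Frame `k` (0-based) is stamped `start_time + k / rate`
throughout the package.

## Kinetics and adaptation

`peak_response()` takes the maximum ΔF/F over frames inside the
stimulation window (earliest frame on ties). Half-rise and half-decay
times interpolate linearly between frames — without interpolation the
metrics quantize to the 0.4 s / 0.125 s frame grids. "Time after
stimulation" is measured from stimulus *onset* (the natural reading, and
the convention used consistently here); half-decay is measured from the
peak time. A trace that never falls to half its peak before the trial ends
gets an explicit `NA`, never a sentinel value. The kinetics operations
refuse traces with `f_peak <= 0`: these metrics are defined for excitatory
responses only, and reduced responses use the other baseline mode upstream.

The adaptation index is `1 - f_offset / f_peak` with `f_offset` sampled at
the frame nearest onset + 19 s (nearest-frame, no interpolation — the
definition pins a time point, and nearest-frame is reproducible). The 19 s
default matches where stimulation offset typically falls for the cell
types this metric was designed around; for longer stimulation windows the
caller supplies the window and lag explicitly, since the appropriate
pairing depends on the experiment.

## Connectivity aggregation

One convention covers all group summaries: average within fly first, then
across flies, unweighted. This equals the grand mean exactly when every
fly contributes equally many trials and deliberately differs otherwise
(each fly is one biological replicate regardless of trial count).
`build_matrix()` applies it per (pre, post) cell at a single stimulation
intensity; mixing intensities is an error, and pairs never tested are
missing (`NA`), never zero — "no response" and "not measured" must stay
distinguishable. `build_segment_map()` fixes the vocabulary to the six
neuromeres (T1L…T3R) for leg-by-neuromere maps. One summary trace per fly
per condition is assumed; if multiple ROIs per fly exist, they should be
combined before matrix construction.

## Joint-angle tracking

The tibia carries a dark pin on a bright background. `binarize_pin()`
thresholds at the midpoint of the robust (1st–99th percentile) intensity
range by default — the plain min/max midpoint is dragged by noise extremes
(the zero floor skews the minimum), which misclassifies a fraction of
background pixels; because second moments weight pixels by squared
distance, even a handful of distant strays corrupts the orientation by
degrees. For the same reason only the largest 8-connected component is
kept by default. Both behaviours are overridable.

`ellipse_orientation()` computes the centroid and normalized second
central moments of the mask in a right-handed image frame (x = column,
y = −row) and reports the long axis of the equivalent ellipse,
$\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\, \mu_{20}-\mu_{02})$
mapped to [0°, 180°), with the standard 1/12 per-pixel variance term that
stabilizes thin masks. Isotropic masks (circle, point, square) have no
defined orientation and raise an error. An ellipse axis is 180°-ambiguous;
a physical tibia flexes to one known side of the femur, so a configured
hinge-side flag resolves the joint angle to [0°, 180°]. The femur
reference axis in image coordinates is a required calibration input — it
cannot be inferred from the pin alone. `resample_to_frames()` linearly
interpolates angles onto imaging frame times, clamping (and counting)
frames outside the video span.

The synthetic leg scene renders the pin with 4×4-supersampled edge
coverage (emulating optical blur) at 200 frames/s on a 160×160 px frame,
pin 60×6 px — proportions like a pin filling a good fraction of a
high-speed camera's view. Joint trajectories span 18°–180°: full flexion
below ~18° is physically obstructed in the preparation this emulates.

## Problem sizes and tolerances in the test suite

Tests run at desk scale, chosen to exercise every code path: movies of
tens of pixels per side and 60–525 frames; the planted-recovery study uses
4 pre sources × 8 post classes × 4 flies over the full six-pulse protocol
(about 210 s at 2.5 frames/s), repeated over 20 seeds at pixel noise 20%
of baseline (per-trace peak SNR well above 10), with binary structure
recovered at a half-maximum threshold and, noiselessly, planted gains
recovered within 2%. Angle recovery is checked at every integer angle
18°–179° (≤ 0.5° noiseless, ≤ 1.5° at noise 10% of contrast); kinetics
closed forms (half-decay τ·ln 2, half-rise at half ramp duration) within
one frame interval; the sliding-window baseline against a brute-force
oracle on 200 random traces. File outputs carry 6 significant digits for
stable diffs.

## Known limitations

Out of scope by design: image registration, neuropil subtraction, bleach
correction, spike deconvolution, photon-accurate noise, DMD spatial
targeting optics, multi-segment pose estimation, and group statistics
(rank tests and the like belong to standard routines downstream of the
emitted CSVs). The generator's fly-to-fly variability is noise-driven
only; it does not model biological gain variation across animals.
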