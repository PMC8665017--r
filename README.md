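# fcmap

Functional connectivity mapping between *Drosophila* leg proprioceptors and
second-order ventral nerve cord (VNC) neurons, from two-photon calcium
imaging.

The femoral chordotonal organ (FeCO) is the fly leg's largest proprioceptive
organ; its club, claw and hook neurons encode vibration, position and
movement direction. Mapping which central VNC neurons (hemilineages such as
9Ba, 10Ba, 13Bb) each subtype drives is done by expressing Chrimson in FeCO
axons, pulsing red light while imaging GCaMP in candidate downstream
neurons, and summarizing the evoked calcium responses. `fcmap` implements
that analysis end to end as a tested R pipeline, together with a seeded
synthetic-data generator that emulates the stimuli and signals, so every
stage is verifiable without raw recordings.

## What it computes

* **ΔF/F extraction** — frames are smoothed with a normalized 5×5 Gaussian
  (σ = 3 px), background-thresholded (Otsu's between-class-variance
  criterion by default), and each ROI's mean fluorescence F(t) is converted
  to ΔF/F = (F − F₀)/F₀, where F₀ is the lowest mean over all contiguous
  10-frame windows of the trial (or the first-10-frames mean, for responses
  that go below rest).
* **Response kinetics** — peak ΔF/F in the stimulation window (F_peak),
  time to 50% of peak after onset, and half-decay time after the peak, with
  linear interpolation between frames.
* **Adaptation index** — 1 − F_offset/F_peak, with F_offset the ΔF/F
  sampled 19 s after stimulus onset: 1 means full decay to baseline during
  sustained stimulation, 0 no adaptation, negative values a growing
  response.
* **Connectivity matrices** — per-trial F_peak values at the plateau
  stimulation intensity (the protocol intensity nearest 0.3 mW/mm², i.e.
  0.28 mW/mm² for the standard six-pulse train) are averaged within each
  fly, then across flies, into a pre-subtype × post-class heatmap or a
  6-leg × 6-neuromere segment map. Untested pairs stay missing, never zero.
* **Vibration tuning** — responses to 4 s sinusoidal tibia vibration
  epochs (two repetitions, 8 s apart) averaged within fly before across
  flies, per frequency; display pixel maps are capped at 300% ΔF/F.
* **Joint-angle tracking** — the pin-marked tibia is segmented by
  thresholding against the bright background, and the femur–tibia angle is
  the orientation of the long axis of the ellipse with the same normalized
  second central moments as the mask, resolved against a configured femur
  axis and hinge side, then resampled onto the imaging timebase.

The synthetic generator drives all of this: GCaMP-like transients are a
duty-cycle-scaled light envelope convolved with a unit-area
difference-of-exponentials kernel, passed through a saturating amplitude
map (optionally with multiplicative adaptation), painted onto disk ROIs
with planted pre→post gains plus Gaussian noise; leg videos render a dark
rotating pin with supersampled edges and known angles.

## Worked example

```r
library(fcmap)
cfg <- run_config(outdir = file.path(tempdir(), "fcmap_demo"), seed = 1,
                  scene = list(noise_sd = 20))
res <- run_demo(cfg)   # simulate -> dff -> metrics -> connectivity -> track -> tuning
res$connectivity
#> Connectivity matrix (pre_by_post) at 0.28 mW/mm^2:
#>         9Ba   10Ba   13Bb
#> club 1.4736 1.1838 0.0360
#> claw 0.0289 0.0396 1.3142
#> flies per cell:
#>      9Ba 10Ba 13Bb
#> club   2    2    2
#> claw   2    2    2
```

The planted connectivity was club→9Ba (gain 1.0), club→10Ba (0.8) and
claw→13Bb (0.9): the recovered matrix shows exactly those cells well above
the noise floor (the ~0.03–0.04 entries), in ΔF/F units — a unit planted
gain yields the model's peak response at 0.28 mW/mm², about 1.45 ΔF/F.
Per-trace kinetics land beside it in `kinetics.csv`, e.g. the fly-1
club→9Ba trace: F_peak 1.46 at the pulse-offset frame, half-rise 0.78 s,
half-decay 3.2 s, adaptation index 0.97 (the 19 s offset sample falls long
after this 5 s pulse has decayed).

Every output directory also contains `provenance.json` (the full resolved
configuration): rerunning any stage from it reproduces the files
bit-identically.

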