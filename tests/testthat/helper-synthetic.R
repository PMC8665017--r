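# Shared fixtures: small scenes, models and layouts built in code.

demo_model <- function(...) gcamp_model(...)

# Single continuous pulse, handy for closed-form checks.
single_pulse_protocol <- function(intensity = 0.28, duration = 30, duty = 1) {
  gen_stimulus_protocol(intensities = intensity, pulse_duration = duration,
                        inter_pulse = 1, duty = duty)
}

# Two disk ROIs wired to a 1x2 planted matrix.
two_roi_layout <- function(radius = 3) {
  list(list(label = "A", center = c(12, 12), radius = radius, pre = "src", post = "A"),
       list(label = "B", center = c(12, 30), radius = radius, pre = "src", post = "B"))
}

two_roi_planted <- function(gA = 1, gB = 0) {
  planted_connectivity(matrix(c(gA, gB), 1, 2,
                              dimnames = list("src", c("A", "B"))))
}

# Brute-force lowest mean over all contiguous `w`-frame windows.
brute_lowest_window <- function(x, w) {
  min(vapply(seq_len(length(x) - w + 1),
             function(i) mean(x[i:(i + w - 1)]), 0))
}

# Independent moment-based orientation (degrees in [0, 180)) from (row, col)
# pixel positions, in the x = col, y = -row frame.
oracle_orientation <- function(pix) {
  x <- pix[, 2]; y <- -pix[, 1]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
}

# Exhaustive between-class-variance search over candidate thresholds.
oracle_otsu <- function(x, candidates) {
  best <- -Inf; best_t <- candidates[1]
  for (t in candidates) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}
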