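---
title: "Detecting alpine-ski turn switches from boot-cuff gyroscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpine-ski turn switches from boot-cuff gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiturn)
```

## The problem

Turns are the basic analytical unit of alpine skiing: almost every
per-turn metric (symmetry, edging, load control) first requires knowing
when each turn begins. The turn switch -- the edge change -- coincides
with the neutral position of the skier's pendulum-like side-to-side
motion, and at the neutral position the roll angular speed of the boot is
at its maximum. A single inertial sensor on the back of each boot cuff
therefore carries enough information to time the switch: the z
(anterior--posterior, "roll") axis of the gyroscope peaks at every edge
change.

`skiturn` implements:

* the two detection algorithms built on this observation (the signed
  **gyroscope z-axis** detector and the unsigned **gyroscope resultant**
  detector),
* the generic semi-automatic windowed extremum search used to screen all
  120 signal variants (2 sensors x 4 axes x 3 sources x 5 filter
  options),
* a **Bland--Altman** evaluation layer with **reference-adjusted
  precision** -- a way of expressing a method's limits of agreement net of
  the imprecision of the (human, video-based) reference it is judged
  against -- and the three-step variant selection rule built on it,
* a **ski-ergometer session simulator** that generates two-boot 6-axis
  IMU records with exact ground-truth switch times, so that the whole
  pipeline is testable end to end without recorded data.

## The detection model

Both detectors share one structure: a *windowing* pass and a *search*
pass, both using zero-lag low-pass Butterworth filters.

**Windowing.** The signal is filtered hard (0.5 Hz for signed axes, 1 Hz
for resultants) so that only the turn-cycle fundamental survives. The
interior local extrema of this trace are the *anchors*; consecutive
anchors delimit one search window per half-cycle. Anchors are only
trusted when their prominence (measured against the segments running to
the neighbouring anchors or record ends) exceeds 5% of the trace's
peak-to-peak range -- zero-phase filtering leaves small ripples within
roughly one filter period of the record ends, and without the guard such
a ripple can masquerade as an anchor and open a spurious window onto
lead-in/lead-out motion.

**Search.** The raw signal is filtered at the analysis cutoff (3 Hz
recommended; 6, 9, 12 Hz and "no filter" are the screening
alternatives). For the z-axis detector, local maxima of the analysis
trace are sought between consecutive strong-filter *minima* and local
minima between consecutive strong-filter *maxima*; the merged, time-ordered
events alternate in sign and each sign maps to a turn direction. For the
resultant detector the anchors are strong-filter minima only and every
window contributes one local maximum; events are unsigned. The resultant
is computed per boot *before* any averaging -- the reverse order would
cancel mirrored motion instead of detecting it.

Within a window, if several candidate extrema survive the optional
prominence gate, the most prominent is kept (one switch per window under
the pendulum model); tied flat extrema resolve to the earliest sample.
Events are sought only between two interior anchors: partial head/tail
windows are ignored, which is also why a recorded (or simulated) trial
must bracket its counted turns with some lead-in and lead-out motion.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff_hz` | 3 | Hz | analysis cutoff; 3/6/9/12 or none |
| `strong_cutoff_hz` | 0.5 (axes), 1 (resultants) | Hz | windowing cutoff |
| `min_peak_prominence` | 0 | signal units | candidate gate inside windows; 5% of the channel IQR is a reasonable noisy-data setting |
| `min_peak_separation` | 0.4 | s | closer events drop the less prominent one; below the shortest half-turn (0.45 s at the 0.90 s tempo) |
| `filter_design` | `order2_filtfilt` | -- | "fourth-order zero-lag Butterworth" read as a 2nd-order design run forward--backward (4th-order effective), the biomechanics convention; `order4_filtfilt` gives the stricter reading |

## Numerical choices

*Zero-lag filtering.* The forward--backward pass uses odd-reflection
padding with steady-state initial conditions (the classic `lfilter_zi`
construction), so a constant series is reproduced exactly from sample
one. The padding length scales with the filter's time constant
(`ceiling(1.5 * rate / cutoff)` samples, capped at the series length):
at the 0.5 Hz strong cutoff on a 50 Hz grid the pole pair decays with a
~0.45 s time constant, and a short fixed pad would leave edge ring-in
strong enough to destroy the anchors of short trials. The effective
magnitude response is the squared single-pass response -- gain 1 at DC,
exactly 1/2 at the cutoff -- and the phase is identically zero, so event
times are not displaced (verified by cross-correlation in the tests).

*Resampling.* Channels are resampled with monotone piecewise-cubic
(shape-preserving) interpolation, which cannot overshoot local extrema
and therefore cannot manufacture spurious peaks. The cost is accuracy
near Nyquist: error stays below 1% of amplitude through about 4 Hz at a
64 Hz input rate (the roll fundamentals are 0.34--0.56 Hz) and grows to
a few percent approaching 10 Hz. Two-boot records are cropped to their
common span and put on one shared grid before averaging.

*Percentiles.* The non-parametric 95% interval uses linear interpolation
of order statistics (R's quantile type 7), fixed in configuration.

*Degenerate inputs.* A constant channel, or one with fewer than two
anchors, yields an empty event series with a warning, not an error; a
window that contains no qualifying extremum is skipped. These are
deliberate choices -- field data can produce all three conditions.

## The evaluation layer

For a detector matched against per-turn reference times (greedy
one-to-one nearest-neighbour pairing, lag-capped at half the median
reference inter-switch interval by default), the package reports the
Bland--Altman bias and 95% limits of agreement, bias +/- 1.96 x SD of
the paired differences (the multiplier is fixed at 1.96, not t-based).

A method cannot be more precise than its reference. The *reference
envelope* is the widest interval over all pairwise rater limits of
agreement (lowest lower limit, highest upper limit). Each measured limit
is then adjusted: limits beyond the envelope contribute their exceedance;
limits inside it are replaced by the envelope (contributing zero); a
measured interval lying entirely beyond one envelope limit discards the
method. The *adjusted precision* is the sum of the two sides, so it is
zero exactly when the measured interval is contained in the envelope --
one can never claim to beat the reference.

Selection then proceeds in three steps: variants whose bias falls outside
the envelope are excluded; variants discarded by the adjustment or with
adjusted precision above 20 ms (one 50 Hz video frame) are excluded; the
lowest adjusted precision wins, with ties broken by smaller absolute
bias, then lower cutoff. Applied to the published screening table shipped
in `variant_loa_table()`, the winner is the averaged-boot gyroscope
z-axis at 3 Hz (adjusted precision 6.6 ms), with the averaged resultant
at 3 Hz next among gyroscope variants (11.6 ms) -- the acceptance tests
reproduce the full table within its printed precision.

## What the simulator emulates, and what it does not

`simulate_session()` prescribes a kinematic inverted pendulum: roll angle
`phi(t) = A cos(pi t / T)` with `T` the turn duration, so the roll rate
`gz = dphi/dt` peaks exactly where `phi` crosses zero -- the edge change.
Ground truth is exact by construction, with switches spaced exactly `T`.
The defaults mirror the laboratory protocol the algorithms were developed
on: 15 counted turns, `T` of 1.45 s (giant-slalom tempo) or 0.90 s
(slalom), and three ergometer attitudes (flat, forward 6.3 degrees, left
5.7 degrees). Slope changes only the accelerometer's gravity projection
(plus a constant roll offset for the left lean), never the roll rate, so
detections must be slope-invariant on noiseless input -- a property the
tests assert. The roll amplitude default of 30 degrees is a package
choice (the protocol does not fix one) and is configurable.

The motion spans a half-turn ramp plus one warm-up edge change on each
side of the counted turns. This is not cosmetic: events are only sought
between two interior anchors, so the first and last counted switches are
detectable only if one more anchor exists beyond each of them, exactly as
a recorded trial brackets its counted turns with lead-in and lead-out
movement. Ground truth covers the counted turns only.

Off-axis gyro channels carry small harmonic leakage (at most 10% of the
roll-rate amplitude), the accelerometer model is gravity projection plus
a centripetal term, and all noise is additive white Gaussian from one
seeded generator (same seed, bitwise-identical session). The right boot
is the left scaled by a configurable asymmetry gain with independent
noise.

`simulate_raters()` turns ground truth into a synthetic multi-rater video
annotation study: per-rater systematic bias plus Gaussian jitter,
quantized to the 20 ms frame grid of a 50 Hz camera, with the per-turn
reference being the rater mean. The default per-rater jitter of 6.3 ms
is calibrated (once) so that the simulated *pairwise rater disagreement*
matches the observed inter-rater study -- pairwise limits-of-agreement
widths of roughly 43--50 ms, i.e. a difference SD near 12 ms after frame
quantization. Note the calibration target is the disagreement *between*
raters, not the per-rater jitter itself: quantization contributes a large
share of the pairwise variance at this scale.

What the simulator deliberately does not model: snow/slope vibration
spectra, multi-plane motion, muscle dynamics (the pendulum is prescribed,
not solved), the sensor's internal analog/digital filter chain, and
rater-specific error structure beyond bias + jitter. Passing tests on
simulated sessions therefore demonstrate the algorithmic contract --
windowing, extremum selection, timing -- not field robustness; the
accelerometer channels in particular exist so accelerometer variants can
be *screened*, not to reproduce their recorded-data agreement values.

## Problem sizes used in the test suite

Simulated sessions use 15 turns (the protocol minimum) at 64 Hz,
resampled to 50 Hz; the noisy-replication property runs 100 seeded
replicates at a noise SD of 5% of the peak roll rate, and the in-window
oracle-equivalence property scans every window of 50 random sessions.
The simulated rater study uses 90 turns (six conditions of 15), matching
the pooled design of the reference study.

## Known limitations

* Timing resolution is one 50 Hz sample (20 ms); sub-sample refinement
  (e.g. parabolic peak interpolation) is out of scope.
* The greedy event pairing is an artifact decision -- the original
  evaluation paired events implicitly via per-turn video reference -- and
  can differ from optimal assignment when detections are badly off.
* Turn *phase* segmentation (initiation/steering/completion), edge-angle
  and load metrics are out of scope, as are acquisition concerns
  (Bluetooth, calibration, orientation estimation).
* Inferential statistics between raters (repeated-measures ANOVA,
  post-hoc tests) are not reimplemented; rater disagreement is reported
  descriptively.

## A worked run

```{r pipeline}
rep <- run_pipeline(run_config(
  synth = list(n_turns = 15, turn_duration = 1.45, noise_sd_gyro = 2),
  variants = c("gyro:z:average:3", "gyro:resultant:average:3"),
  seed = 42, log_level = "quiet"))
rep$variant_table[, c("variant", "n_detected", "bias",
                      "loa_lower", "loa_upper", "adj_total", "fate")]
rep$selection$winner[, c("sensor", "axis", "cutoff_hz", "adj_total")]
```
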