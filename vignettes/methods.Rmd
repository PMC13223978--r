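---
title: "Methods: activity, gait and PTIBS pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity, gait and PTIBS pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigait)
```

This vignette documents the analysis conventions the package implements, the
assumptions behind them, and the scope and limits of the synthetic-data
generators used to validate the pipeline.

## Signal model and preprocessing

All recordings are uniformly sampled single channels (`signal_channel`):
angular acceleration in °/s² from trunk-mounted IMUs (nominally 2 kHz,
placements thoracic T4 and lumbar L3, with an axis map naming the yaw and
medio-lateral components) and hip angles in degrees from electro-goniometers
(nominally 1 kHz, 0° = upright anatomical reference, flexion positive).
Delimited-text I/O (`read_signal_channels()`) infers the rate from the median
time step, requires strictly increasing time stamps with at most 1 % step
non-uniformity, and warns when the inferred rate deviates more than 1 % from
the nominal one.

Three primitives are shared by every downstream analysis:

* **Resampling** (`resample_signal()`). IMU channels are brought to the
  1 kHz goniometer grid. When downsampling, an 8th-order zero-phase
  Butterworth anti-alias filter at 0.45× the target rate is applied, then
  the signal is evaluated on the new grid by cubic-spline interpolation.
  We replaced a polyphase FIR resampler after measuring ~2–3 % passband
  ripple; the spline path round-trips band-limited test signals with
  < 0.1 % RMS error.
* **Savitzky–Golay smoothing** (`savgol_filter()`): local least-squares
  polynomial fit, 3rd order over a 0.051 s frame. The frame is specified as
  a duration so the same smoothing scale applies at any rate (103 samples at
  2 kHz, 51 at 1 kHz; the sample count is forced odd). By construction the
  filter reproduces polynomials up to its order exactly, which the test
  suite verifies to ~1e−13 on random cubics.
* **Zero-phase low-pass** (`butterworth_lowpass()`): 4th-order Butterworth
  at 10 Hz applied forward and backward (`filtfilt`), so the effective
  magnitude response is squared and the phase is exactly zero — event
  timing (gait extrema) is not biased by filter lag. Because the underlying
  `filtfilt` has no initial-condition matching, the input is extended by odd
  reflection (12× rate/cutoff samples per side) so start-up transients fall
  in discarded padding; a constant record passes through to ~1e−10.

## Physical activity

The dorsal-plane magnitude is the absolute value of the Savitzky–Golay
smoothed yaw channel. Each sample is assigned an intensity by half-open
binning:

| Level | Interval (°/s²) |
|-------|-----------------|
| Rest  | [0, 5)          |
| Low   | [5, 50)         |
| High  | [50, ∞)         |

Boundary convention: a sample at exactly 5 °/s² is *Low* and at exactly
50 °/s² is *High* (intervals closed on the left). Session summaries report
the three time fractions (summing to 100 %), the non-rest percentage
(Low + High), and — when a Baseline session for the same animal and
placement exists — recovery as 100 × session non-rest / Baseline non-rest.
A zero-activity Baseline yields `NA` recovery with a warning rather than an
infinity.

## Walking-bout detection and gait cycles

Walking is detected from the thoracic medio-lateral channel (resampled to
1 kHz, 10 Hz low-passed) in non-overlapping 5 s FFT blocks, giving 0.2 Hz
frequency resolution. Frequency bins below 0.4 Hz are excluded (postural
drift), and a block is *walking* when its dominant remaining frequency lies
in the closed locomotor band [2.5, 4.0] Hz. Adjacent walking blocks merge
into bouts; a bout's dominant frequency is taken from its strongest block.

We read the 2.5–4 Hz band as the *step* frequency of the trot-like porcine
gait. A single hip's angle cycles once per stride, and with steps at ~3 Hz
the generator therefore uses a 0.6 s hip cycle: a 3 Hz *cycle* rate would
put cycle durations (0.33 s) outside the package's own plausibility bounds
of [0.4, 2] s, so the step-frequency reading is the only self-consistent
one.

Within walking bouts, hip cycles are delimited **peak flexion to peak
flexion**: local maxima with prominence ≥ 10° (`find_peaks()`), cycle
duration restricted to [0.4, 2] s, and at most 10 cycles per session taken
in chronological order. Each cycle is linearly interpolated onto 101 points
(0, 1, …, 100 % of cycle) and summarized by maximum (peak flexion), minimum
(peak extension), range of motion, and the cycle percentages of the extrema
(first occurrence on ties). A session is eligible for gait analysis only
when the aggregated PTIBS score exceeds 3 *and* at least 3 valid cycles
exist; the representative cycle is the pointwise mean ± SEM curve with
metrics averaged over per-cycle metrics (not taken from the mean curve,
which would underestimate extrema when peaks are asynchronous).

**A note on `pct_at_max` in the peak-delimited frame.** Because every cycle
*starts* at a flexion peak, the maximum of a noisy cycle falls at ~0 % or
~100 % essentially at random, and the average of per-cycle `pct_at_max` is
uninformative (≈ 50 by symmetry). Extension timing is still well defined:
`pct_at_min` measures the flexion-to-extension interval from the delimiting
peak. The synthetic ground truth therefore records timing in both frames
(`pct_at_min` as prescribed on the template, and `pct_at_min_peakframe =
(pct_at_min − pct_at_max) mod 100` in the frame the pipeline observes), and
validation compares like with like.

Baseline-relative deltas (`gait_delta()`) are percentage changes with a
*signed* baseline denominator, 100 × (post − base) / base, for the angle
metrics, and plain point differences for the timing metrics. With a signed
denominator, a post-injury extension of −9.6° against a Baseline of −15°
reports −36 % — a *reduction* in extension — which matches how such changes
are conventionally reported; an absolute-value denominator would flip the
sign for negative baselines.

## PTIBS

The 10-level rubric (bundled as `inst/extdata/ptibs_rubric.json`) partitions
into hindlimb *dragging* (1–3), *stepping* (4–6) and *walking* (7–10), with
behavioural anchor descriptors per level; `score_level()` maps a descriptor
to its level. Observer scores must be integers in 1–10; the per-animal score
is the mean (optionally median) across observers, and the category is
reported only when all observers agree, otherwise `"mixed"`. Group summaries
are mean ± SEM with the sample (n − 1) standard deviation; change from
Baseline averages per-animal deltas, so every animal needs a Baseline score.

## Synthetic data: scope and limits

The generators are *statistical emulators of the measurement process*, not
biomechanical simulations. They exist so each pipeline stage can be checked
against known ground truth.

* **Activity sessions** interleave rest/low/high epochs carrying exact
  scheduled time fractions. Within an epoch, the yaw magnitude follows a
  slowly varying (2 Hz knot) curve drawn uniformly *inside* the target bin
  with safety margins (rest [0.5, 4], low [7, 45], high [55, 150] °/s²), a
  constant sign per epoch, and additive Gaussian noise (SD 0.5 °/s²). The
  margins keep the post-smoothing signal inside its bin, so recovered
  fractions converge to the schedule; they do not model bin-straddling
  behaviour, which real animals certainly produce.
* **Gait sessions** superimpose three components on all channels: walking
  bouts (medio-lateral sinusoid at the step frequency, cosine-tapered over
  0.3 s at bout edges), a postural-sway background (0.8 Hz, 8 °/s²)
  present throughout, and white noise. The sway term is deliberate: a
  noise-only background is spectrally flat, so after 10 Hz low-passing its
  dominant frequency lands in the 2.5–4 Hz band by chance in a
  non-negligible fraction of 5 s blocks. Real resting animals are not
  spectrally flat — slow postural adjustments dominate — and modelling that
  makes non-walking blocks correctly classified for the right reason rather
  than by tuning the detector.
* **Hip angles** follow a piecewise-cosine template passing *exactly*
  through the prescribed extrema (peak flexion 25° at 40 % of cycle, peak
  extension −15° at 85 %, by default): half-cosine arcs between consecutive
  extrema guarantee the template's maximum and minimum equal the prescribed
  values with zero overshoot. A cubic-spline template was rejected because
  spline overshoot between knots changes the very quantities the validation
  is supposed to recover. The right hip is the left shifted by half a
  cycle.
* **Studies** (`generate_study()`) write a four-animal design (P1–P3
  injured, P4 control) over Baseline / 2-day / 14-day sessions with
  session-level effect sizes (activity-fraction shifts, flattened hip
  template, PTIBS trajectories) and a `manifest.json` recording every
  ground-truth parameter. Per-session seeds derive deterministically from
  the study seed, so regeneration is byte-identical.

Defaults match the study conditions (30-minute activity sessions at 2 kHz,
1 kHz goniometry). Examples and report-level tests in this package use
scaled-down sizes (e.g. 6-second activity sessions, 20–30 s gait sessions)
purely to keep documentation and test runtime proportionate; this is the
package's own choice, and the acceptance checks for activity-fraction
recovery run on full 30-minute sessions.

## Determinism and provenance

`run_study()` embeds a provenance block: an MD5 hash of the analysis
parameters (thresholds, gait configuration, aggregation rule, seed — the
data and output directories are locations, not parameters, and are
excluded), the seed, and the package version. `write_report()` emits only
content-determined bytes (no timestamps), so identical configuration + seed
reruns produce byte-identical report bodies wherever the files live.

## Parameter reference

| Parameter | Default | Units | Where |
|---|---|---|---|
| IMU sampling rate | 2000 | Hz | recording / generators |
| Goniometer sampling rate | 1000 | Hz | recording / generators |
| Analysis grid | 1000 | Hz | `resample_signal()` |
| Savitzky–Golay order / frame | 3 / 0.051 | – / s | `savgol_filter()` |
| Butterworth order / cutoff | 4 / 10 | – / Hz | `butterworth_lowpass()` |
| Rest/Low and Low/High thresholds | 5 / 50 | °/s² | `activity_thresholds()` |
| FFT block length | 5 | s | `gait_config()` |
| Walking band | [2.5, 4.0] | Hz | `gait_config()` |
| Minimum analysed frequency | 0.4 | Hz | `gait_config()` |
| Peak prominence | 10 | deg | `gait_config()` |
| Cycle duration bounds | [0.4, 2] | s | `gait_config()` |
| Cycles per session | 10 | – | `gait_config()` |
| Normalized cycle length | 101 | points | `normalize_cycle()` |
| Eligibility | PTIBS > 3 and ≥ 3 cycles | – | `gait_eligibility()` |
| PTIBS levels / observers | 10 / 3 | – | rubric / study design |
| Activity session length | 30 | min | `study_design()` |

## Limitations

* Cycle segmentation assumes reasonably clean goniometry; severe artefacts
  that survive the 10 Hz low-pass can masquerade as flexion peaks.
* Walking detection classifies 5 s blocks; bouts shorter than a block, or
  gait slower/faster than the 2.5–4 Hz band (severely impaired stepping),
  are not detected, which is intentional — the gait metrics are defined for
  locomotor-band walking only.
* The generators validate the pipeline's arithmetic, not its biological
  validity; tolerances met on synthetic data say nothing about sensor
  placement, skin motion or cross-talk in real recordings.
* Recovery percentages compare each animal to its own Baseline and are
  undefined (reported `NA`) when the Baseline shows no activity.
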