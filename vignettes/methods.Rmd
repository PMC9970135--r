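---
title: "Quaternion-based respiratory rate estimation and activity recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternion-based respiratory rate estimation and activity recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatresp)
```

## The measurement model

Three IMUs stream unit quaternions at 10 Hz: a thoracic and an abdominal
unit on the chest wall, and a reference unit on the lower back that moves
with the trunk but is not deformed by breathing. Breathing manifests as
small (degree-scale) periodic rotations of the chest-wall units relative
to the trunk. Expressing each chest-wall orientation in the reference
frame,

$$ {}^{U}_{R}\hat q(t) \;=\; {}^{U}_{E}\hat q(t) \otimes {}^{R}_{E}\hat q(t)^{*}, $$

cancels every rotation the three units share (posture, sway, gait) and
leaves the residual breathing rotation plus whatever the cancellation
cannot remove: sensor noise and small unit-specific motion. All quaternion
algebra uses the Hamilton product with scalar-first components. Neither
convention choice is observable in the output — the referencing identity
holds under both — but fixing one keeps every intermediate value
reproducible. Relative series are renormalized and sign-canonicalized
(`w >= 0`): the two antipodal quaternions represent the same rotation, and
without the convention a stream can flip between them mid-recording,
injecting artificial steps into the baseline.

The estimation chain, per compartment, is: 97-sample moving-average
baseline removal per component; PCA to one respiratory waveform; an
adaptive low-frequency threshold from inter-peak statistics of the
smoothed waveform; Welch spectral peak search between the merged
threshold and an activity ceiling; a ±0.04 Hz band-pass around the
located peak; and tuned peak detection giving breath-by-breath RR
(`60 / Δt` between consecutive maxima). The thorax–abdomen sum of the two
band-passed waveforms is processed identically (with the thoracic tuning)
and serves as the headline estimate: it aggregates both compartments and
is robust to artifacts confined to one of them.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| baseline window | 97 | samples | moving-average span (9.7 s) tracking residual non-breathing movement |
| SG smoothing | order 3, 31 | samples | noise reduction before inter-peak statistics, peak-shape preserving |
| threshold floor `f_thresh_min` | 0.05 / 0.2 / 0.4 | Hz | static / walking & cycling / running; rejects movement artifacts below plausible breathing |
| search ceiling | 1.0 / 0.75 / 1.4 | Hz | static / walking & cycling / running; upper bound of plausible breathing |
| Welch | 300-sample window, 50 overlap, Hamming | samples | 30 s segments; 0.033 Hz bin width |
| band half-width | 0.04 | Hz | adaptive band-pass around `f_peak` |
| band-pass | Butterworth order 2, forward–backward | — | zero phase preserves breath peak timing; effective order 4 |
| second SG window | odd(0.6 · fs / f_peak), ≥ 5 | samples | scales smoothing with the breathing period |
| min peak distance | 0.5 / f_peak | s | suppresses double-detections within half a breath |
| min prominence | 0.2 · sd(band-passed signal) | — | scale-free floor against ripple |
| low-SNR flag | peak < 3 × median in-band PSD | — | marks unreliable spectra rather than failing |
| HAR window | 200 | samples | 20 s of 10 Hz data |
| split / seed | 80/20, seed 42 | — | reproducible train/test partition |
| KNN / RF / SVM | k = 5 / Gini / RBF σ = 1 | — | classifier defaults |

The threshold, band, Welch, windowing, split, and classifier values are
the validated configuration of the processing algorithm this package
implements; the breath-detection tuning map (`0.6`, `0.5`, `0.2` factors)
is this package's own default where the original tuning is not published
in closed form, and every factor is a `rr_config()` key.

## Numerical choices

- **Moving-average edges.** The 97-sample window shrinks symmetrically at
  the recording boundaries instead of padding, so no fabricated baseline
  appears at the edges.
- **Spectrum input.** The Welch PSD and the band-pass act on the raw PCA
  waveform; the order-3/31-sample smoother feeds only the inter-peak
  threshold statistics. At 10 Hz that smoother has its first stopband
  null near 0.55 Hz and would otherwise erase the breathing peaks of
  dynamic activities (0.5–0.85 Hz) before the spectrum analysis.
- **PCA sign.** PC1 is oriented so its correlation with the first raw
  component is non-negative (ties: positive first loading) —
  deterministic across platforms.
- **Spectral ties.** The PSD argmax breaks ties toward the lower
  frequency (the first maximum on the ascending frequency grid).
- **Peak timing.** Detected maxima are refined by quadratic interpolation
  through the three samples around each peak (shift clamped to ±0.5
  samples). Without it, breath intervals are quantized to the 10 Hz grid
  (±1.5 breaths/min per breath at 42 breaths/min); with it, a noise-free
  simulated recording is recovered to the breath-count quantization limit
  of `60 / duration` breaths/min.
- **Exact self-cancellation.** The Hamilton product is evaluated with the
  term grouping under which `q ⊗ q*` cancels exactly in floating point,
  so self-referencing yields the identity series with zero error.
- **Degenerate inputs.** All-constant component matrices are a PCA error;
  fewer than 3 threshold peaks fall back to the preset floor with a flag;
  a flat detection signal returns an empty, flagged breath table rather
  than an exception; constant HAR channels standardize to zero with a
  warning; kurtosis and skewness of a constant window are defined as 0.
- **Standardization.** Uses the population (1/n) standard deviation, the
  common machine-learning scaler convention.

## Open design points, as resolved here

- **Per-compartment peak.** `f_peak` and the band are computed separately
  for thorax and abdomen; only the low threshold is merged (by minimum).
  The two compartments genuinely breathe with different amplitude and
  slightly different phase, so a shared peak would favor one of them.
- **Merged threshold symbol.** The lower band edge uses the merged
  (minimum) threshold; a per-compartment variant is one configuration key
  away.
- **Metric averaging.** Classification precision/recall/F1 are
  macro-averaged: robust to the residual class imbalance kept in the
  single-unit configuration.
- **Standardization before splitting.** Fitted on the whole dataset
  before the 80/20 split, following the stated preprocessing order of the
  original pipeline. This leaks scaling statistics into the test set;
  `standardize_windows(dataset, params)` accepts parameters fitted on any
  subset for a leakage-free protocol.
- **Stair climbing.** Maps to the walking preset (walking-like cadence
  and breathing range). Its characteristically poor signal-to-noise ratio
  is modeled in the simulator (tripled sensor noise) and surfaces through
  the low-SNR quality flag instead of a hard failure.
- **Label encoding.** Classes are encoded in lexicographic order.
- **Gap handling.** Counter gaps up to 10 samples (1 s) are filled by
  component-wise linear interpolation plus renormalization — within
  1e-3 of spherical interpolation for the degree-scale rotations involved
  — and longer gaps raise an error naming the interval rather than
  interpolating through seconds of missing motion.

## What the simulator emulates — and what it does not

Each scenario composes: a per-task base posture orientation; slow
postural sway (0.6–0.8°, 0.02–0.03 Hz) shared by all units; for dynamic
tasks a gait oscillation (roll at cadence, pitch at twice the cadence,
half amplitude; walking ≈ 1.6–1.9 Hz, cycling 1.5 Hz, stairs 1.4 Hz,
running 2.8 Hz) also shared; compartment-specific breathing rotations —
2° on the dominant compartment and 0.8° on the other, thorax-dominant
upright and abdomen-dominant in horizontal postures; a small
unit-specific gait "leak" (3% of the gait amplitude) representing
imperfect motion cancellation between separately strapped units; white
per-sample angular noise (0.15°, tripled for stairs); and Bernoulli
transmission dropouts (2%) that reappear as counter gaps. Ground truth
travels in a sidecar file, never in the quaternion log.

The rotation amplitudes are free parameters — the study protocol does not
quantify chest-wall rotation — chosen once for realistic signal-to-noise.
The leak fraction was initially set to 10% of the gait amplitude, which
made the differential inter-unit motion exceed the non-dominant breathing
rotation and contradicted the premise that referencing cancels trunk
motion; it was reduced once to 3%, the plausible magnitude of residual
differential trunk rotation, and not revisited.

Not modeled: biomechanical gait detail, breath-to-breath rate
variability, sensor-fusion drift and magnetic disturbance, posture
transitions within a recording, and correlated (bursty) packet loss.
Passing tests therefore demonstrate that the pipeline recovers known
rates under controlled, stationary conditions with realistic noise — not
performance on free-living data.

## Problem sizes

The validation grid uses twenty 300 s recordings (3000 samples per unit),
five per preset, spanning 12–50 breaths/min. The activity-recognition
reference corpus uses five synthetic subjects × twelve tasks × 300 s,
giving 900 windows (750 after balancing) of 96 three-unit time features
or 60 single-unit time + frequency features. Unit tests run on
500–6000-sample fixtures.

## Known limitations

- Respiratory rate below the preset floor or above the ceiling is
  invisible by construction; a mismatched preset degrades gracefully
  (low-SNR flag, out-of-band estimate) but is not auto-corrected inside
  `estimate_rr()` — the CLI `pipeline` subcommand provides the
  HAR-driven preset selection.
- The median RR of very short recordings is breath-count limited; the
  Welch stage needs at least 300 samples (30 s).
- Linear gap interpolation degrades during fast gait: a lost sample of a
  2.8 Hz oscillation cannot be reconstructed on a 10 Hz grid, which is
  visible as broadband artifact in a single compartment. The sum
  estimate is the recommended headline value for dynamic recordings.
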