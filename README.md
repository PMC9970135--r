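# quatresp

Respiratory-rate estimation and human activity recognition from a wearable
system of three orientation-streaming inertial measurement units (IMUs):
one on the thorax, one on the abdomen, and a reference unit on the lower
back. Each unit transmits a unit quaternion at 10 Hz; breathing appears as
degree-scale micro-rotations of the chest wall riding on much larger trunk
motion. The package is aimed at researchers in wearable physiological
monitoring who need a tested, scriptable implementation of the full
quaternion-to-breathing-rate chain, the companion activity classifier, and
a synthetic-data simulator to validate both end to end.

## The method

**Respiratory rate (RR).** For each chest-wall unit the orientation is
re-expressed in the reference unit's frame,

```
q_rel(t) = q_unit(t) ⊗ q_ref(t)*   ,
```

(`⊗` Hamilton product, `*` quaternion conjugate), which cancels trunk
motion common to all units and leaves the breathing rotation. The chain
then runs, per compartment:

1. baseline removal — a centered 97-sample moving average is subtracted
   from each quaternion component;
2. dimension reduction — PCA; the first principal component is the
   respiratory waveform;
3. adaptive threshold — the waveform is Savitzky–Golay smoothed (order 3,
   31 samples), the inverses of inter-peak distances give frequency
   statistics, and `f_thresh = max(f_thresh_min, f_mean − f_std)` with an
   activity-dependent floor (0.05 Hz static; 0.2 Hz walking/cycling;
   0.4 Hz running). The two compartment thresholds are merged by their
   minimum;
4. spectral peak — Welch PSD (Hamming window, 300 samples, 50 overlap);
   `f_peak` is the PSD maximum between the merged threshold and an
   activity ceiling (1 / 0.75 / 1.4 Hz);
5. adaptive band-pass — `f_U = f_peak + 0.04 Hz`,
   `f_L = max(f_thresh_m, f_peak − 0.04 Hz)`, order-2 Butterworth applied
   forward–backward;
6. breath detection — a second, `f_peak`-tuned Savitzky–Golay pass, then
   maxima/minima detection with tuned minimum peak distance and
   prominence. RR is reported breath by breath as `60 / Δt_peak`, for the
   thorax, the abdomen, and the sum of the two filtered signals.

**Activity recognition (HAR).** Raw quaternion channels (4 per unit) are
standardized (`x_std = (x − μ)/σ`), cut into non-overlapping 200-sample
(20 s) windows, and summarized per channel by 8 time-domain features
(mean, sd, variance, kurtosis, skewness, peak-to-peak, median, IQR) plus,
optionally, 7 FFT-based frequency features. After merging the protocol
tasks to 10 classes and (for the three-unit configuration) balancing to
the smallest class, a seeded 80/20 split feeds KNN (k = 5, Euclidean),
random forest (Gini), and an RBF-kernel SVM
(`K(X₁,X₂) = exp(−‖X₁−X₂‖²/2σ²)`, σ = 1).

**Simulator.** Since no recordings ship with the package, a scenario-based
generator emulates the twelve-task study protocol (seven static postures,
five dynamic activities; 5 min each): posture orientation ⊗ trunk sway ⊗
gait oscillation, compartment-specific breathing rotations at a controlled
rate, per-sample sensor noise, and counter-gap transmission dropouts, with
ground truth in a sidecar file.

## Worked example

```r
library(quatresp)

sim <- simulate_recording(scenario("walking_4kmh", rr_bpm = 22, seed = 7))
sim$recording
#> <recording> subject=sim  label=walking_4kmh  fs=10 Hz  n=3000 (300.0 s)

estimate_rr(sim$recording, "walking")
#> <rr_result> subject=sim  preset=walking
#>   thorax  median RR =  22.0 bpm  (109 breaths, band [0.327, 0.407] Hz)
#>   abdomen median RR =  22.0 bpm  (110 breaths, band [0.327, 0.407] Hz)
#>   sum     median RR =  22.0 bpm  (109 breaths, band [0.327, 0.407] Hz)
```

The adaptive band has locked onto the true breathing frequency
(22 breaths/min = 0.367 Hz) and the walking preset has excluded the
1.6 Hz gait cadence; all three signals agree on the median RR. For
activity recognition:

```r
corpus <- simulate_har_corpus(subjects = 3, seed = 7, duration = 120)
metrics <- har_pipeline(corpus, units = "all", seed = 42)
metrics$rf
#> <eval_metrics> rf: accuracy=1.000 precision=1.000 recall=1.000 F1=1.000
```

A command-line wrapper with the same functionality (subcommands
`simulate`, `rr`, `har-features`, `har-train`, `har-eval`, and `pipeline`,
which chains predicted activity → preset → RR estimation) is installed at
`system.file("cli", "quatresp.R", package = "quatresp")`.

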