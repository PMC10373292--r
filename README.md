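# cardiowave

Feature extraction and rotor analysis for cardiomyocyte-monolayer
electrophysiology in R.

Cultured monolayers of (stem-cell-derived) cardiomyocytes are routinely
characterized by two complementary recordings: **optical mapping** —
high-speed fluorescence movies of voltage (e.g. FluoVolt) or calcium
(e.g. Cal 520) reporters — and **multi-electrode arrays (MEA)** recording
extracellular field potentials on a grid. From these, electrophysiologists
quantify action-potential duration (APD30, APD90 and their ratio, the
classic index separating triangular atrial-like from plateaued
ventricular-like morphology), beat period, field-potential duration with
Fridericia rate correction (FPDc), spike amplitude, conduction velocity,
and — after burst pacing induces reentry — the lifetimes of spiral-wave
rotors and their organizing centers, the phase singularities.

cardiowave implements that entire analysis chain:

* **Optical conditioning** — per-pixel sliding-window normalization,
  masked Gaussian smoothing, zero-phase 4th-order Butterworth band-pass
  (1–30 Hz, forward + reverse), Hanning edge tapering, optional truncated
  Fourier re-synthesis.
* **Phase mapping** — Hilbert-transform instantaneous phase; phase
  singularities by the double-ring criterion (cumulative wrapped phase
  differences > π on two concentric Bresenham rings); greedy
  nearest-neighbor singularity tracking; wavefront extraction with
  lifetime and death-cause statistics; recording-level rotor reports.
* **AP features** — beat detection at maximum dF/dt with sub-frame
  refinement, APD at arbitrary repolarization fractions via an
  isotonic-regression crossing estimator with a segmented (plateau /
  phase-3 / tail) beat fit, ensemble (signal-averaged) beat analysis,
  tidy per-beat and per-replicate tables.
* **MEA features** — spike detection, FPD to the repolarization
  deflection (polarity-agnostic), exact Fridericia correction
  `FPDc = FPD / (RR/1 s)^(1/3)`, conduction velocity by least-squares
  plane fit of activation times, vehicle-adjusted paired drug deltas.
* **Synthetic ground truth** — an Aliev–Panfilov reaction–diffusion
  simulator (planar waves, cross-field spiral induction, burst pacing)
  with an independent isopotential-intersection spiral-tip oracle,
  analytic AP traces with closed-form APD truth, and kinematic
  electrogram synthesis — so every estimator is validated against known
  truth without any external data.

## Worked example

Simulate a paced monolayer, synthesize electrograms over a 4×4 electrode
grid, and recover conduction velocity and FPDc; then measure APDs on a
noisy synthetic atrial-like trace:

```r
library(cardiowave)

par  <- medium_params(grid_height = 64, grid_width = 64, seed = 1)
prot <- stimulus_protocol("planar_s1", onset_ms = 10, period_ms = 800,
                          count = 3)
sim  <- simulate_medium(par, prot, 2600)
sim$ground_truth$plane_velocity_cm_s
#> 13.8

eset <- synth_electrograms(sim)
fp   <- fp_features(eset, min_period_ms = 300)
m    <- merge(fp, eset$geometry, by = "electrode")
conduction_velocity(data.frame(x_mm = m$x_mm, y_mm = m$y_mm,
                               t_ms = m$spike_time_ms, beat = m$beat))
#> <conduction_estimate> 13.3 cm/s (residual 0.03 ms RMS, 16 electrodes)

ap <- synth_ap_trace(apd30_ms = 84, apd90_ms = 160, beat_period_ms = 639,
                     n_beats = 5, noise_sd = 0.02, seed = 1)
tf <- trace_features(ap$value, ap$time_ms, min_period_ms = 300)
tf[1:3, c("activation_ms", "apd30_ms", "apd90_ms", "apd_ratio",
          "beat_period_ms")]
#>   activation_ms apd30_ms apd90_ms apd_ratio beat_period_ms
#> 1        200.16    83.97   160.05      0.52         638.24
#> 2        838.41    83.97   160.05      0.52         639.40
#> 3       1477.80    83.97   160.05      0.52         639.56
```

The estimated conduction velocity (13.3 cm/s) matches the simulator's
ground-truth planar velocity (13.8 cm/s) within 4%, and the recovered
APDs match the generator's analytic truth (84 / 160 ms, ratio 0.53)
within a fraction of a frame despite 2% noise.

For rotors: `simulate_medium()` with a `cross_field_s2` protocol
produces sustained reentry; `preprocess_movie()`,
`instantaneous_phase()`, `detect_singularities_movie()`,
`track_singularities()` and `rotor_report()` take the movie to a
recording-level summary of singularity and wavefront lifetimes.

A pipeline front end is included: `run_pipeline(config, out_dir)` runs
simulate → preprocess → ap → phase → mea from one YAML-style
configuration with full provenance (config hash in every output file,
byte-identical reruns under a fixed seed), and `exec/cardiowave` exposes
the same as a shell command.

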