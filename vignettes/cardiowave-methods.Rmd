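---
title: "Methods: optical mapping, rotor detection and MEA analysis in cardiowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical mapping, rotor detection and MEA analysis in cardiowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cardiowave quantifies the electrophysiology of cultured cardiomyocyte
monolayers from two kinds of recordings: fluorescence movies of voltage or
calcium reporters (optical mapping), and extracellular electrograms from
multi-electrode arrays (MEA). Because raw recordings of this kind are
rarely redistributable, the package also ships a ground-truth generator —
an excitable-medium simulator plus analytic trace and electrogram
synthesizers — so that every stage of the analysis can be validated
against known truth. This vignette explains the models, the estimators,
their tunable parameters, and the choices made where the design was open.

## The synthetic excitable medium

The simulator integrates the two-variable Aliev–Panfilov model, the
standard minimal description of cardiac excitation for wave and spiral
dynamics:

$$\partial_t u = D \nabla^2 u + [k u (u-a)(1-u) - u v]/\tau$$
$$\partial_t v = \epsilon(u,v)\,[-v - k u (u-a-1)]/\tau,\qquad
  \epsilon(u,v) = \epsilon_0 + \mu_1 v/(u + \mu_2)$$

with normalized transmembrane variable $u \in [0,1]$ and recovery variable
$v$. Defaults are $k=8$, $a=0.1$, $\epsilon_0=0.002$, $\mu_1=0.2$,
$\mu_2=0.3$ — a parameter set long used for stable spiral waves — with
diffusion $D = 0.1\ \mathrm{mm^2/ms}$, pixel size $dx = 0.6$ mm,
$\tau = 12.9$ ms per dimensionless time unit, and forward-Euler step
$dt = 0.25$ ms, which respects the explicit stability bound
$dt \le dx^2/(4D)$ (the constructor enforces it). Boundaries are no-flux
(mirrored), matching the edge of a cultured monolayer. On the default
128×128 grid the planar conduction velocity is ≈ 14 cm/s, within the range
reported for iPSC-derived monolayers.

Three stimulation protocols are provided: repeated planar edge pulses
(`planar_s1`), the classic cross-field S1/S2 spiral induction
(`cross_field_s2`; with default kinetics an S2 at 650 ms into the S1
repolarization tail yields one sustained rotor), and `point_burst` pacing
(10 Hz for 30 s corresponds to `period_ms = 100, count = 300`).

Ground truth is recorded as the simulation runs: per-pixel activation
times (upward crossings of $u = 0.5$, linearly interpolated between saved
frames), per-pixel APD90 (time above $u = 0.1$), and — crucially — the
spiral-tip trajectory computed by an *isopotential-intersection oracle*:
a tip at frame $t$ is the exact geometric intersection of the marching-
squares contours $u_t = 0.5$ and $u_{t-1} = 0.5$, with chirality from the
cross product of the two spatial gradients. This oracle shares no code
with the phase-based detector it later validates.

The optical forward model (`optics_model`) applies gain, baseline,
mono-exponential photobleaching and additive white Gaussian noise, and
decimates to the camera interval (default 5 ms/frame, the acquisition
rate of the recordings the pipeline targets). The generator's noise
defaults are free parameters, not calibrated values — no amplitude or
noise statistics for real recordings were available to fit them.

All indices in the R API and in exported CSV files are 1-based, R's
native convention.

## Optical conditioning chain

`preprocess_movie()` applies, in order:

1. **Sliding-window normalization** (window 100 frames, i.e. 0.5 s at
   5 ms/frame): each pixel is min–max rescaled within a centered,
   truncated window. This equalizes amplitude across the field and is
   invariant to per-pixel gain and offset. Truncation (not padding) at
   the movie ends avoids phase bias. The rolling extrema use a
   sparse-table scheme, so full-frame movies remain cheap.
2. **Masked spatial Gaussian** (default $\sigma = 1$ px, no printed value
   exists for the source pipelines, so it is exposed in the
   configuration): normalized convolution, in which masked pixels neither
   contribute nor receive — constants are preserved up to the mask edge.
3. **Zero-phase Butterworth band-pass**, 4th order, 1–30 Hz, applied
   forward and reverse (`signal::filtfilt`), after mean removal and a
   Hanning taper of the trace ends. The first and last
   $\lceil 2 f_s / f_\mathrm{low} \rceil$ frames (two periods of the low
   cut) are flagged untrusted; phase analysis skips them.

A truncated Fourier re-synthesis (`smooth_recompose`, keep the $K$
largest in-band components, default $K = 25$) is available as an optional
smoothing step. It is disabled in the AP-feature path: beat-level feature
extraction operates on the (optionally band-passed) trace directly.

## Phase mapping and rotor statistics

The instantaneous phase is the argument of the analytic signal (FFT
Hilbert construction) of each mean-free pixel trace, wrapped to
$(-\pi,\pi]$. Phase singularities — rotor cores — are detected with a
double-ring criterion: the wrapped phase differences are accumulated
around two concentric Bresenham circles (defaults $r_{in}=2$,
$r_{out}=4$ px; the radii are not prescribed by the method's sources and
are configurable), and a singularity is declared where both ring sums
exceed $\pi$ in magnitude with equal sign. An ideal singularity winds by
$2\pi$; the $\pi$ threshold tolerates discretization. Each connected
cluster of candidate pixels becomes one detection at the cluster
centroid — the centroid rather than the maximal pixel, because for an
ideal vortex every pixel whose rings encircle the core attains the same
winding and the tie-broken pixel can sit ≈ 1.5 px off core.

Tracking is greedy nearest-neighbor (closest pairs first) with a
same-chirality constraint, `max_link_px = 10` and gap bridging up to 2
frames — adequate for the ≤ 10 simultaneous singularities these
preparations show; global assignment would only matter at much higher
densities. Wavefronts are the 8-connected components of activation
isophase crossings (default $\varphi_{act} = \pi/2$; the choice moves the
front geometrically but does not affect singularity detection), linked
across frames by overlap after 2-px dilation, with death causes labelled
boundary / singularity / collision. `rotor_report()` aggregates both raw
per-frame detection counts and linked-track counts, since published
transient-singularity counts may follow either convention.

Validation: on 50 random planted-vortex fields the detector must agree
with an independent per-plaquette winding oracle in count, position
(≤ 1 px) and chirality; on a simulated cross-field rotor the dominant
phase track must stay within 5 px RMS of the isopotential tip oracle and
cover ≥ 90% of trusted frames, while 10 Hz planar pacing of the same
medium must produce no track longer than 50 ms. The test suite runs these
at 128×128 with 8 s (rotor) and 6 s (planar) of simulated time.

## Action-potential features

Beats are detected at the maximum upstroke derivative; a parabola through
the three derivative samples around the maximum refines the activation
below the frame interval (ties resolve to the earliest sample). Merging
keeps the larger-amplitude event when two candidates fall within
`min_period_ms`. The noise floor for candidate upstrokes is estimated
from second differences, which smooth tissue-level upstrokes barely
excite.

APD at fraction $f$ is measured from activation to the first post-peak
crossing of $\mathrm{peak} - f\,(\mathrm{peak} - \mathrm{baseline})$,
with the diastolic baseline taken as the median of the 30% of the
preceding inter-beat interval closest to activation, and no rate
correction (rate correction is applied to field potentials only). The
crossing estimator is built for noisy optical traces:

* a 3-point running median removes single-frame spikes;
* an antitonic (decreasing isotonic) regression of the post-peak segment
  gives a provably monotone repolarization fit, whose level crossings are
  therefore monotone in $f$;
* a continuous three-segment piecewise-linear beat fit (plateau, rapid
  phase-3 repolarization, diastolic tail; breakpoints grid-searched with
  the line parameters profiled out by least squares) refines the crossing
  and the peak. The fitted plateau line is extrapolated to the midpoint
  between activation and the first decay sample, which approximates the
  true AP peak for both sharp-peaked and plateaued morphologies;
* `trace_features()` pools amplitude and baseline across beats by median
  (they are slowly varying trace-level properties) and, by default,
  measures APDs on the activation-aligned *ensemble average* of all
  detected beats — the signal-averaged AP standard in optical mapping.
  Per-beat activation, period and amplitude are always per beat; set
  `ensemble = FALSE` for beat-to-beat analyses such as alternans, and
  `refine = FALSE` in `compute_apd()` for strongly curved phase-3
  morphologies where a linear segment fit is inappropriate.

The synthetic AP generator returns closed-form truth: a raised-cosine
upstroke (maximal derivative exactly at its midpoint, the activation
reference), a slowly declining plateau, and a single straight phase-3
segment through the requested APD30 and APD90 crossing levels. Its
acceptance-test configuration draws APD90 from 130–400 ms with an
APD30:APD90 ratio increasing with duration (0.35–0.65) — short
triangular APs and long plateaued APs, mirroring the atrial/ventricular
morphology spectrum — with noise SD uniform in 0–5% of amplitude, 5 beats
per trace at 1.1 s period, 5 ms frames. Under these conditions ≥ 95% of
beats recover both APD30 and APD90 within one frame (5 ms), and APD is
monotone in the fraction for every beat. Single-beat estimation cannot
reach that bound at the top of the noise range (an exact-model fit has a
≈ 4 ms error SD at 4.5% noise on shallow shapes), which is why ensemble
averaging is the default.

Calcium transients use the same machinery with fraction defaults
{0.5, 0.9}; dye polarity is declared (`polarity = -1` for dimming dyes)
and all features are invariant under it.

## MEA field-potential metrics

Depolarization spikes are detected on the absolute trace derivative with
a MAD-based adaptive threshold floored at 25% of the largest deflection
(so that clean traces do not admit every sample), refined to sub-sample
precision by parabolic interpolation; amplitude is max − min within
±10 ms. FPD is the interval from spike to the largest absolute excursion
from the local baseline inside (spike + 50 ms, next spike − 50 ms) —
the repolarization deflection's peak, polarity-agnostic, with parabolic
sub-sample refinement. The peak (rather than the deflection's end) is the
measured endpoint; the alternative end-of-wave convention is noted in the
configuration. Rate correction uses Fridericia's cube-root formula with
RR in seconds: $\mathrm{FPDc} = \mathrm{FPD} / (RR/1000)^{1/3}$, exact by
construction (270 ms at RR 729 ms gives 300 ms).

Conduction velocity comes from a least-squares plane fit
$t(x,y) = t_0 + p x + q y$ over electrode positions in mm; speed is
$1/\sqrt{p^2+q^2}$ (reported in cm/s), direction the unit gradient, and
per-beat fits are averaged. A global plane is appropriate for uniform
monolayer propagation over a small grid; local gradient methods are a
possible extension, not implemented. Collinear electrode sets raise an
error; near-zero gradients (above `v_max_cm_s`, default 1000) are flagged
unresolvable rather than reported as spuriously fast. With ten beats on a
4×4, 1-mm grid and 0.5 ms timing jitter, speeds of 10–80 cm/s are
recovered within 5%, and a 45°-rotated wave agrees with the axis-aligned
one within 1%.

Paired drug effects are vehicle-adjusted ratios of ratios,
$\Delta = (m_\mathrm{post}/m_\mathrm{pre}) /
(v_\mathrm{post}/v_\mathrm{pre})$, per matched electrode, so drift shared
with vehicle wells cancels; absolute differences are reported alongside.

## Pipeline, reproducibility and replicate tables

`run_pipeline()` executes simulate → preprocess → ap → phase → mea in
fixed order from a single validated configuration; every artifact carries
the MD5 hash of the canonicalized configuration, and identical
configuration + seed yields byte-identical outputs (the test suite checks
file hashes). Movies are written as 16-bit multi-page TIFF with a JSON
sidecar recording the affine intensity map, mask, frame interval and
provenance; electrograms as CSV (`time_ms` plus one column per electrode
named `r{row}c{col}`) with a JSON geometry sidecar.

`aggregate_replicates()` concatenates per-replicate summaries into a long
table keyed by protocol, line, differentiation (N) and technical
replicate (n), with per-protocol descriptive summaries explicitly
labelled as such. Statistical inference on those tables (mixed-effects
models, estimated marginal means, contrasts) is deliberately out of
scope: the package's contract ends at the tidy replicate table such fits
consume. The command-line front end (`exec/cardiowave`) is a thin wrapper
over `run_pipeline()` with one subcommand per stage. One YAML caveat: the
replicate identifiers `N` and `n` must be written quoted (`"N": 3`) in
configuration files, since YAML 1.1 parses bare `n`/`N` as booleans.

## Problem sizes and limitations

The shipped validation uses 64×64 phase fields, 128×128 reaction-
diffusion grids with 6–8 s of simulated activity, 200 synthetic AP traces
and 4×4 electrode grids — sizes chosen so the whole suite runs on a
laptop-class single core in minutes while still exercising sustained
reentry end to end.

What the synthetic data do not emulate: motion artifacts (no contraction
in the model), ratiometric or strongly bleaching dyes beyond the
mono-exponential envelope, spatially correlated noise, fibrotic or
heterogeneous tissue, electrode impedance variation, and pacing
artifacts on stimulated MEA wells. Passing the synthetic validation
therefore demonstrates correctness of the estimators under the stated
forward models, not robustness to every artifact of real recordings.
Aliev–Panfilov kinetics reproduce wave phenomenology, not specific ionic
currents; no claims about particular channels follow from it.
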