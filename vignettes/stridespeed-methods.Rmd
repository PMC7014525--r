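---
title: "Estimating per-stride canter speed from one saddle IMU: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-stride canter speed from one saddle IMU: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridespeed)
```

## The problem

A rider wants the speed of each canter stride from a single inertial unit
at the pommel of the saddle — no GPS (useless indoors), no magnetometer,
no limb-mounted sensor. Direct integration of acceleration is not viable
here: off a treadmill there is no steady-state assumption to pin down the
integration constants, and a trunk-mounted sensor never sees the
zero-velocity instants a foot sensor would. `stridespeed` implements the
two estimators that remain practical, and the protocol for comparing
them.

## Stride windows

The dorso-ventral (z) accelerometer axis shows one dominant impact peak
per canter stride. Each detected peak anchors a window of that sample
plus the following 100: a 6 × 101 matrix (channels ax, ay, az, gx, gy,
gz by samples; 1 s at 100 Hz). Two deliberate properties:

* **No resampling.** A fast stride completes in fewer samples, so its
  window contains more than one movement cycle. Cycle count and cycle
  shape inside a fixed-duration window are themselves speed information;
  normalising the cycle length would destroy it.
* **Overlap allowed.** When consecutive peaks are closer than 101
  samples, each still anchors its own window (the default). A window is
  an observation unit, not a partition of the recording. A non-overlap
  mode (`segmentation_config(allow_overlap = FALSE)`) exists for
  sensitivity analysis.

The peak detector is a local-maximum search with two guards, both
configurable because no canonical parameterisation exists for this
sensor placement: a **topographic prominence** floor (default 1 g —
well below the main impact peak, well above within-cycle secondary
oscillations) and a **minimum separation** (default 0.35 s, shorter than
any plausible canter stride; when two candidates are closer, the taller
wins, ties resolved in sample order by the decreasing-height scan).
Prominence rather than absolute height makes detection invariant to a
constant bias on the axis. Peaks too close to the end of the recording
to support a full window are dropped. Sample indices are 1-based
throughout, following R convention; a window spans the closed interval
`[anchor, anchor + 100]`.

## The ODBA baseline

Overall dynamic body acceleration is a classic signal-based proxy for
locomotor effort. Per window:

1. **Low-pass filter** each acceleration axis: Butterworth, order 4,
   10 Hz cut-off, applied forward and backward so the pass is zero-phase
   and rectified means are not smeared across the window. The package
   implements the forward-backward pass itself (steady-state initial
   conditions plus odd-reflection padding of 3 × order samples) because a
   naive zero-state pass leaves a visible startup transient on a
   101-sample window.
2. **Gravity alignment**: rotate all acceleration samples by the single
   minimal rotation (about the axis normal to the plane of the two
   vectors) that takes the *window-mean* acceleration vector onto +z.
   The mean over a full stride is dominated by gravity, so this
   estimates sensor tilt without any attitude filter or gyroscope
   fusion. Estimating it per window rather than per session tracks
   slow posture changes; the rotation is unique, deterministic and
   norm-preserving. If the mean magnitude falls below 0.1 g (free-fall,
   corrupt data) the direction is undefined and the window is rejected.
3. **Mean-subtract, rectify, sum, average**: per axis subtract the
   window mean, take absolute values, sum the three axes per sample,
   average over the 101 samples. The result is a non-negative scalar in
   g; it is zero exactly when each filtered, aligned axis is constant.

Speed is then an ordinary least-squares line `v = β₀ + β₁·ODBA`
(`fit_odba_model()`, a plain `lm()` underneath, with `tidy()`/`glance()`
accessors). One subtlety worth knowing: the rectified three-axis sum is
an L1 quantity and is *not* rotation-invariant, which is why the gravity
alignment step matters and why closed-form checks must be constructed
with the mean already on +z.

## The ν-SVR window model

The window is flattened channel-major (101 ax samples, then ay, az, gx,
gy, gz → 606 features) and passed to ν-support-vector regression
(`e1071::svm`, libsvm underneath). Parameter interpretation:

* **cost = 4** — the smoothness/regularisation constant of the SVR
  objective.
* **ν = 0.75** — bounds the fraction of training points that become
  support vectors; with ν-regression the ε-tube half-width is then
  chosen by the optimiser rather than fixed a priori.
* **radial-basis kernel, γ = 1/606** — one over the feature dimension,
  the standard libsvm default.
* **Per-feature standardisation** (training-set mean/variance) is on by
  default: raw features mix g and deg/s scales. Zero-variance columns
  are excluded from scaling. Standardisation makes predictions invariant
  to any consistent per-feature affine rescaling of the inputs.

The first two are surfaced in `svm_config()` precisely because their
naming varies across toolchains; the remaining choices (kernel, γ,
scaling) are this package's documented defaults, not claims about any
particular prior implementation.

## Evaluation protocol

`repeated_holdout()` runs, by default, 50 repetitions of a uniform
random 80/20 split at the stride level; train and test are disjoint by
construction. Per repetition and method it records:

* **% errors above threshold** — strictly greater than 0.6 m/s by
  default; an error of exactly the threshold does not count.
* **RMSE**.
* **Bland–Altman 95% limits of agreement** — differences oriented
  `predicted − measured`, bias ± 1.96 × sample (n−1) SD; the report
  keeps the width of that interval. For Gaussian errors the width
  converges to 3.92σ, which the test suite checks at n = 10⁵.

Summaries follow the convention of reporting mean/min/max of the
percentage error and mean (SD) of RMSE and LoA width *across repetition
means*, not across pooled strides. The master seed deterministically
spawns one sub-seed per repetition, so adding repetitions never changes
earlier ones. Stride-level splitting lets strides of one horse appear on
both sides — faithful to the protocol being reproduced, but optimistic
about generalisation to unseen horses; `group_by_horse = TRUE` provides
the stricter split rather than changing the default silently.

## The synthetic generator

`simulate_canter()` builds a 100 Hz recording whose dorso-ventral axis
is gravity plus a two-harmonic periodic waveform,
`a(v)·(cos θ + 0.4·cos 2θ)/1.4`, with phase θ advancing as the integral
of a speed-dependent stride frequency. The other five channels carry
phase-shifted harmonics of the same oscillation plus noise. Defaults,
chosen once as plausible for canter and kept fixed:

| parameter | default | rationale |
|---|---|---|
| speed range | 4–9 m/s | spans competition canter speeds with margin |
| stride frequency | `1.4 + 0.12·v` Hz | ~2 Hz mid-range, rising gently with speed, within the 0.5–4 Hz band the config enforces |
| z peak amplitude | `0.5 + 0.25·v` g | stronger impacts at speed; keeps |az| ≤ 4 g, inside the ±8 g sensor range |
| amplitude jitter | 5% log-normal, per recording | movement vigour varies between horses and passes at the same speed; this is the main reason an amplitude-based estimator cannot be perfect |
| sensor noise | 0.05 g / 2 deg/s | white, small relative to signal |
| curve share | 10% of recordings | minority protocol, as in a mixed straight/curved database |
| within-curve fluctuation | 3% relative, one slow cycle | a horse does not hold a commanded speed exactly; the broadcast curve-average label is therefore slightly wrong per stride, on purpose |

The second harmonic gives each cycle an asymmetric, multi-peaked shape
(its secondary bump has ~0.08·a prominence, safely under the 1 g
detection floor) while the global maximum stays exactly at θ = 0 — so
ground-truth peak positions are known analytically and the noiseless
closed loop (simulate → detect) must recover them to ±1 sample.

`reference_error_injection()` adds reference-system uncertainty: straight
speeds get a 1.4% multiplicative Gaussian error (the stated relative
accuracy of a camera-based reference, i.e. ±2.8 cm at 2 m), curve groups
share one timing perturbation (0.5% relative), since the whole curve is
timed once.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: jump efforts and landing transients,
terrain and surface variation, gait transitions and irregular rhythms,
sensor bias drift and saddle slip, and any biomechanically validated
canter kinematics. The generator's purpose is narrower: to provide
signals where speed information is present in window content in the same
*structural* way (frequency, amplitude, cycle count) with known truth,
so the pipeline's correctness and the two methods' relative behaviour
can be verified end to end. The directional result — the window SVR
beating the ODBA line on all three metrics — is expected to transfer;
the absolute error levels are not.

## Numerical and degenerate-input choices

* Filtering a signal shorter than 3 × order + 1 samples is an error, not
  a silent fallback.
* `gravity_align` rejects windows with mean acceleration below 0.1 g;
  antipodal means (straight down) rotate by π about x.
* Out-of-range samples (beyond ±8 g / ±2000 deg/s) are *findings* from
  `validate_recording()`, never clipped and never blocking: the ranges
  are a sensor spec, not a data filter.
* Timestamps may jitter up to 10% of the nominal period before a
  recording is rejected as non-uniform.
* Degenerate fits fail loudly: fewer than two strides, all-identical
  ODBA values, or all-identical feature rows are errors.
* Serialised SVR models carry a format version tag checked on load.

## Problem sizes

The test suite exercises the full protocol at 800 synthetic strides ×
50 repetitions (the package's reference configuration for the method
comparison) and uses a shared 300-stride dataset for module-level
checks; metric oracles run on 1000 random vectors and the LoA
convergence check at n = 10⁵. `scripts/acceptance.R` reruns the
800-stride protocol from scratch at any seed.

## Known limitations

Stride anchoring assumes canter-like dominant periodicity on z; walk and
trot are out of scope, as is per-limb event detection. The SVR carries
no per-prediction uncertainty. Models trained at 100 Hz windows do not
transfer to other sampling rates (recordings at other rates are rejected
rather than resampled). Horse-level generalisation should be assessed
with `group_by_horse = TRUE`, at the cost of fewer effective training
animals.
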