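---
title: "Methods: Kalman-filtered IMU fall detection with a Bayes-network classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kalman-filtered IMU fall detection with a Bayes-network classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imufall)
```

## The sensing model

A single sensor board worn at the top of the trunk samples tri-axial
acceleration (in g) and angular velocity (in deg/s) at 100 Hz — human
activity has essentially no spectral content above 20 Hz, so 100 Hz
oversamples comfortably.  The trunk-fixed X axis is the longitudinal axis:
standing, X is parallel to gravity and the accelerometer reads about
(1, 0, 0) g; lying, X is perpendicular to gravity.  Three derived features
summarise posture and movement at each sample:

* resultant acceleration $a(t) = \sqrt{a_x^2 + a_y^2 + a_z^2}$ (g),
* trunk angle $\theta(t) = \cos^{-1}\!\big(a_x / \sqrt{a_x^2+a_y^2+a_z^2}\big)$
  (degrees, in $[0, 180]$),
* resultant angular velocity
  $\omega(t) = \sqrt{\omega_x^2 + \omega_y^2 + \omega_z^2}$ (deg/s).

The trunk angle treats the measured acceleration as gravity-dominated; it
is a posture estimate, not an orientation tracker, and is exactly the
quantity that sweeps from about 0° to about 90° during a fall.  A
zero-magnitude acceleration vector has no defined angle; since a working
accelerometer at rest reads about 1 g, the package treats ‖a‖ = 0 as
corrupt data and raises an error rather than returning a sentinel.

## Noise identification and the Kalman filter

MEMS inertial sensors carry non-negligible, serially correlated
measurement noise.  The package identifies it from a static calibration
recording (sensor at rest, recommended ≥ 2 min): each axis is fitted with
autoregressive models of order 1–3 and the order is chosen by Akaike's
final prediction error,
$\mathrm{FPE} = \hat\sigma^2\,(n+p+1)/(n-p-1)$.

Two estimation details are deliberate choices.  The estimator is
conditional least squares (regression of $x_t$ on its $p$ lags, no
intercept) after mean removal; Yule–Walker is available as a config
alternative and agrees to $O(1/n)$.  Mean removal matters because the
acceleration axes carry a constant gravity offset: a near-unit-root AR fit
on an uncentred series is ill-posed, so the mean is estimated separately
and carried as a state offset.  `fit_ar()` therefore reports the series
mean alongside the coefficients.

For static IMU noise the FPE differences between AR(1), AR(2) and AR(3)
are tiny — same decade — so `select_order()` keeps the *lowest* order whose
FPE is within a relative factor (default 2×) of the best candidate.  This
operationalises "prefer the simplest adequate model" as a reproducible
rule; a genuine 1000× improvement still switches order.

The selected AR(1) models parameterise a discrete Kalman filter per
3-axis channel: $A = \mathrm{diag}(a_1^{(x)}, a_1^{(y)}, a_1^{(z)})$,
$Q = \mathrm{diag}(\mathrm{FPE}_x, \mathrm{FPE}_y, \mathrm{FPE}_z)$ (used
exactly, no rounding), $H = I$ (states observed directly), zero control
input, and a configured measurement-noise diagonal $R$ — $R$ is not
identifiable from the calibration alone, so it is an explicit input with
reference defaults ((2e−5, 2e−5, 3e−5) g² for acceleration,
(0.002, 0.00087, 0.00109) (deg/s)² for the gyro).  Acceleration and
angular velocity run as two independent 3-state filters; no
cross-covariance is modelled.

Numerical choices:

* **Initialisation** is from the data: $x_0$ = first measurement,
  $P_0 = R$.  This avoids a transient (a constant stream passes through
  bit-identically) and nothing downstream depends on start-up behaviour.
* **State offset**: when the parameters carry no explicit offset the
  filter removes each stream's own per-axis means and restores them on
  output; a fixed calibration offset can be supplied instead.  With
  $a_1 \approx 1$ the two differ negligibly, but the per-stream choice
  makes the filter exact on constant input.
* **Covariance conditioning**: the standard (not Joseph-form) update is
  used, with re-symmetrisation $(P + P')/2$ each step; the diagonal
  parameterisation keeps this benign, and tests assert symmetry to 1e−12
  and convergence of the covariance recursion to the discrete algebraic
  Riccati fixed point to better than 1e−8.
* Because $A, Q, R, H$ are all diagonal the 3-axis filter decouples into
  three scalar recursions; the implementation exploits this for speed and
  the matrix predict/update operations remain the reference path in tests.

Exact unit-root coefficients ($a_1 = 1$, a random-walk state) are
permitted without special-casing — rounding in a calibration report cannot
be distinguished from a true unit root, and the filter is well-defined
either way.

## Windowing and feature sets

Falls complete in under 2 s, so the stream is segmented by a sliding
window of `window_duration(fs, 2)` samples — 200 at 100 Hz — advanced one
sample per arrival in deployment.  Indices are 0-based and half-open:
window $k$ covers $[k\,\mathrm{step},\, k\,\mathrm{step} + \mathrm{width})$,
giving $\lfloor (n - w)/s \rfloor + 1$ windows.  Three per-sample feature
sets are configured: FS9 (all six axes plus $a$, $\omega$, $\theta$), FS7
(axes plus $\theta$), FS3 ($a$, $\omega$, $\theta$ only).

For *training and evaluation* the default is one window per recording
(centred on the recording, whose templates centre the activity), not every
step-1 window: overlapping windows of one recording are near-duplicates,
and counting them as independent instances would both leak across
cross-validation folds and overstate the evidence.  Per-arrival sliding
remains the deployment mode and is available via
`window_select = "all"`.  Windows are materialised as plain matrix slices
(R's copy-on-modify semantics make explicit views unnecessary).

## The classifiers

Two classifiers share one interface.  **Gaussian naive Bayes** fits a
per-class normal density per feature (variance floored at 1e−6 to survive
degenerate features).  The **Bayes network** discretizes each feature into
equal-frequency bins (default 10; bin edges from training quantiles, ties
may merge bins) and learns a class-augmented structure: the class node is
a root parent of every feature node and up to `max_parents` (default 1)
feature-to-feature edges per node are added by greedy hill-climbing under
a decomposable Dirichlet-marginal (K2-style, pseudo-count α = 0.5) score,
rejecting cycle-creating edges.  CPTs are smoothed maximum likelihood with
the same α, so no cell is ever zero; at prediction time out-of-range
values clip into the nearest edge bin.  With `max_parents = 0` the network
reduces *exactly* to discretized naive Bayes — a reduction the tests pin
against an independently coded oracle.

The joint factorises as $P(C, X_1..X_n) = P(C)\prod_i P(X_i \mid \pi_i)$
and is evaluated in log space throughout: a 200-sample window under FS9
multiplies 1800 likelihood factors, far past linear-space underflow.

A window is labelled either by the argmax of the window-averaged log
joint (`mean_log_posterior`, default — repeated-evidence aggregation) or
by majority vote of per-sample argmaxes.  *All ties break towards a fall
class*: in a safety application a tie must alarm.  Per-sample
classification with window aggregation was chosen over training on
flattened 1800-dimensional window vectors; it matches the per-time-point
feature framing and keeps the CPTs well-estimated.

## The synthetic corpus

Real fall corpora are collected on padded surfaces with briefed
volunteers and are rarely distributable, so the package ships a
phenomenological simulator rather than recordings.  Each class is a
deterministic template — a trunk-angle trajectory $\theta^*(t)$, the
gravity projection it implies ($a_x = \cos\theta^*$, with the in-plane
component routed to Y for sideward falls and Z for backward movements),
class-specific half-sine acceleration bursts, and angular-velocity
envelopes whose dominant axis carries $d\theta^*/dt$ — plus per-subject
execution jitter (amplitude, timing, gait frequency and phase) and
stationary AR(1) noise on all six channels with coefficients and
innovation variances taken from the reference calibration (unit roots
nudged to 0.999 to keep long recordings stationary).

Design values: 4 s recordings with the activity centred at 2 s; walking
at a 1 Hz gait with resultant acceleration staying above 1 g; fall
trunk-angle transitions of ~0.7 s (well under the 2 s bound) ending at
90°; an impact transient along the instantaneous gravity direction that
makes the peak resultant acceleration exactly the `impact_g` parameter
(default ≈ 2 g); fall angular-velocity peaks (≳250 deg/s, with the
sharpest axis being ω_x for the backward fall) exceeding every ADL's
(≲90 deg/s).  The default corpus shape is 100 recordings per class over
20 subjects (5 repetitions each), 600 recordings.

What the simulator does *not* emulate: inter-subject biomechanical
diversity beyond scalar jitter, soft-tissue and garment artefacts,
sensor saturation and dropout, near-fall confounders (stumbles,
sitting down hard), or unscripted ADLs.  Consequently the corpus is
near-separable by construction: cross-validated accuracies here are
upper bounds demonstrating pipeline correctness and the *ordering* of
configurations (more features ≥ fewer; filtered ≥ raw), not forecasts of
real-world performance.  Accuracy on undistributed human recordings is a
property of those recordings and is deliberately not claimed.

## Evaluation

Cross-validation is stratified at the *recording* level — the corpus's
600 elements are recordings, and letting one recording's windows span the
train/test divide would leak.  Folds are dealt per class (sizes within
one), the classifier is trained on the stacked per-sample vectors of the
training recordings' windows, each test recording's window is classified,
and confusions accumulate.  Ablations (`ablation_report()`) reuse one
fold assignment across configurations so differences are attributable to
configuration alone.

Metrics follow the field's split reporting: six-class accuracy (exact
class), fall sensitivity (true falls predicted as *any* fall — a subtype
confusion still alarms, so it counts for sensitivity while remaining a
six-class error), specificity (ADLs predicted as any ADL), and the
fall-vs-ADL binarisation's TP/FP rates.  These binarised definitions are
the only ones under which reported sensitivities can exceed every
per-subtype accuracy, which is why they are adopted.  No inferential
testing is performed; reports are descriptive.

Third-party baselines (k-NN, decision trees, bagging) can be compared
through the same window instances with any external library; the package
does not re-implement them.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (default 17): corpus
generation, fold shuffling, noise.  The test suite exercises AR recovery
at n = 20 000 (coefficients 0.5/0.9/0.99 within 3 standard errors),
Riccati convergence for both reference channels, classifier oracles on
2-feature/3-bin/2-class problems, and a full 600-recording, 10-fold,
three-configuration ablation — sizes chosen to estimate every quantity
well while keeping the whole suite comfortably fast on a single CPU.

## Known limitations

* The trunk angle is the only orientation estimate; no quaternion or
  sensor-fusion tracking (by design — it is the feature the classifier
  needs, not a navigation state).
* $R$ is a configured constant; nothing in the package estimates it.
* The Bayes network handles discretized evidence only; hybrid
  (continuous-parent) networks are out of scope.
* Stair ascent/descent resemble walking with different peak values and
  are not among the six default classes.
* The simulator is phenomenological, not biomechanical; see above for
  what that implies about reported accuracies.
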