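---
title: "Methods: gait-phase segmentation and freezing-of-gait detection from a foot IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-phase segmentation and freezing-of-gait detection from a foot IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`fogait`, the assumptions behind them, the parameters that matter, what
the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result beyond what the package's tests and acceptance script compute
themselves.

## 1. Signal model and frames

The input is a six-channel recording from a single inertial sensor on
the instep of one foot: specific force $a(t)\in\mathbb{R}^3$ in m/s²
(gravity included) and angular rate $\omega(t)\in\mathbb{R}^3$ in rad/s,
both in the sensor frame, on a uniform grid (nominally 200 Hz). The
sensor is mounted with $z$ up and $y$ pointing against the walking
direction, so the mediolateral axis is $x$ and the foot's long axis is
$y$.

**Euler convention.** Angles are extracted as intrinsic
$z\!-\!x'\!-\!y''$: yaw about the vertical, *pitch about the
mediolateral ($x$) axis*, roll about the long axis. With the mounting
above, a positive rotation about $+x$ raises the heel, so pitch is
positive when the heel is above the toes — the clinically meaningful
sign. A conventional aerospace $z\!-\!y'\!-\!x''$ sequence would put
"pitch" about the foot's *long* axis under this mounting, which is why
the package deviates from it. Gimbal lock sits at pitch $\pm 90°$, far
outside the range of gait.

## 2. Orientation estimation

`update_orientation()` is a complementary filter: the quaternion is
propagated by strap-down integration of the angular rate (callers use
the midpoint rate $\tfrac12(\omega_{k-1}+\omega_k)$, making the
integration second order) and then rotated toward the measured gravity
direction about a horizontal axis. Because the correction axis is
horizontal, yaw is never constrained and drifts slowly, as expected
without a magnetometer.

Two parameters matter:

* `tau_acc` (s, default 0.5) — the correction time constant. A static
  tilt error decays as $e^{-t/\tau}$, i.e. converges in roughly 2 s,
  matching the design target for recordings that begin seated.
* `acc_gate` (m/s², default 0.5) — the correction is applied only when
  $\bigl|\,\lVert a\rVert-g\,\bigr|$ is below this gate. During swing
  the specific force is dominated by linear acceleration; an ungated
  filter tilts toward it and leaks gravity into the horizontal
  channels, which corrupts the strap-down velocity on the order of
  0.5 m/s per swing and silently breaks the velocity-based
  motion-end condition. Gating on the norm is the standard remedy and
  costs nothing at rest, where the correction does its work.

Gravity $(0,0,g)$ is removed in the global frame *before* offset
estimation, because strap-down velocity integration needs gravity-free
acceleration and the rest offsets should only absorb residual bias, not
gravity itself. During detected rest phases, offsets of the global
acceleration, angular rate and Euler angles are the moving average of
the last $n_d = 10$ samples (fewer while the window fills); outside
rest they are frozen. Before the first rest phase all offsets are zero.

## 3. The gait-phase state machine

Three phases: **rest** (no foot activity), **unrest** (activity), and
**motion** — a sub-phase of unrest spanning an effective displacement or
orientation change, corresponding to the swing phase (toe-off → initial
contact) in regular gait. Parkinsonian motion phases can also be
shuffling steps or heel lifts from shank trembling.

All thresholds are the published single operating point
(`gpd_params()`), used unchanged for every recording:

| parameter | value | role |
|---|---|---|
| $a_\mathrm{rest}, \omega_\mathrm{rest}$ | 0.5 m/s², 0.11 rad/s | rest bounds (condition A) |
| $n_r$ | 10 samples | debounce for A, F, G |
| $\varphi_p$ | 1° | motion-start pitch maximum bound |
| $\Delta$ | 0.25 s | roll/acceleration peak pairing window |
| $a_s$ | 2 m/s² | filtered-acceleration peak height |
| $n_a$ | 7 samples | acceleration-norm moving average |
| $\alpha,\beta$ | 1.2, 0.6 | jerk / velocity factors (D1, D2) |
| $t_\mathrm{mot}$ | 0.075 s | minimum motion duration before end checks |
| $\varphi_r,\kappa$ | 5°, 0.8 | pitch-minimum end condition (E) |
| $t_x$ | 0.1 s | no-rest interval before Z reactivation |
| $p_1, p_2$ | 0.75 °/s, 1.5 | Z conditions F and G bounds |
| $\varphi_\mathrm{thres}$ | 15° | Z condition H pitch maximum |
| $n_d$ | 10 samples | rest offset window |

Decisions taken where the published description leaves room:

* **Unrest debounce.** The rest direction of condition A is explicitly
  $n_r$-debounced; the reverse transition is treated symmetrically
  ($n_r$ consecutive supra-threshold samples).
* **Local extrema** are defined operationally as a sign change of the
  first difference confirmed by one sample, ties breaking toward the
  earlier sample. Detection therefore lags a peak by one sample; phase
  boundaries are placed at the peak sample itself, which keeps the
  per-sample output causal (prefix runs reproduce full runs exactly).
* **D1 maximum.** The end condition compares the current jerk against
  $\alpha\,\max_{\tau\in[t_0,\,t-1]} j(\tau)$. Including the current
  sample in the maximum would make the condition unsatisfiable for
  $\alpha>1$.
* **D2** compares against running maxima that include the current
  sample, which is equivalent for any $\beta<1$ and matches the printed
  form.
* **Condition F units.** The bound $p_1$ is printed in °/s while the
  condition is written on angles. The printed unit governs: by default F
  tests the pitch and roll *rates* ($|\dot\varphi| < p_1$);
  `gpd_params(f_on_angles = TRUE)` switches to the literal angle
  reading.
* **Condition G** uses a sliding variance of the *raw* acceleration
  norm over $n_r$ samples (window length reuses the debounce constant,
  which is otherwise unstated), debounced by $n_r$ like F. The bound
  $p_2 = 1.5$ is printed with the unit m/s² but bounds a variance; its
  coherent unit is m²/s⁴ and the value is kept verbatim.
* **$a_s$** appears in the parameter table but nowhere in the published
  text; it is used here as the minimum height of the filtered
  acceleration-norm peak in the roll/acceleration start condition — the
  only acceleration threshold without a home.
* **Truncation.** A motion phase still open when rest begins or the
  recording ends is closed at that boundary and flagged `truncated`.
* The condition letter "C" is absent from the published description
  (letters jump from B to D1); no operation corresponds to it here
  either.

The reactivation state Z is active on entering unrest, deactivates at
each motion end, and reactivates — enabling the search for the *next*
motion start inside the same unrest interval — after $n_r$ consecutive
samples of F or G once $t_x$ has elapsed without rest, or immediately on
a pitch maximum above $\varphi_\mathrm{thres}$ (H). This is what
segments festination, where steps follow each other with no intervening
rest. Bookkeeping invariant: motion starts per unrest interval = 1 +
Z reactivations in it.

## 4. Features and ranking

Per completed motion phase, in fixed order: maximum of
$\lVert a_{d,g}\rVert$; maximum and minimum pitch; stride length;
maximum gait velocity; turning angle; turned flag; maximum and mean
turn rate; step duration.

* **Strap-down velocity** is the cumulative trapezoid of $a_{d,g}$ from
  $v(t_0)=0$. The **drift correction** subtracts a linear-in-time ramp
  per axis so $v(t_\mathrm{end})=0$ exactly — equivalent to removing a
  constant accelerometer bias over the phase, which is all the
  zero-end-velocity constraint can identify. The stride vector is the
  integral of the corrected velocity; stride length is the norm of its
  horizontal part. The correction is exact (machine precision) for any
  polynomial velocity contaminated by linear drift; through the
  trapezoid rule the full chain is exact for accelerations of degree
  ≤ 1 plus a constant bias (the trapezoid rule itself is not exact for
  higher-degree integrands, so no stronger claim is made or tested).
* **Maximum gait velocity** uses the horizontal speed
  $\lVert(v_x,v_y)\rVert$: the transverse plane is the gait-relevant
  plane and the vertical channel carries the contact transient.
* **Turning** is detected on the yaw angle referenced to the phase
  start, unwrapped across $\pm180°$: the flag is set when yaw changes
  monotonically (tolerance 1°, accommodating sensor noise), never
  re-crosses zero after leaving it, and ends beyond the tolerance. The
  turning angle (final yaw) is always reported, turned or not.
* **Turn rates** are $|\dot\psi|$ (max and mean); the absolute value
  avoids sign cancellation in the mean over a phase.
* **Chi-square ranking**: each feature is discretised into 10 quantile
  bins (fewer if it takes fewer values) and tested for independence
  against the binary label (Pearson, no continuity correction);
  importance is $-\log_{10} p$. The relevance bar 1.3 corresponds to
  $p<0.05$ only in base-10 logarithms, which fixes the logarithm base.
  Constant features get importance 0 with a warning.

Lagged design matrices (C₋₂,₋₁,₀: 30 columns; C₋₂,₋₁: 20 columns with
the label from the current phase) drop rows lacking predecessors rather
than zero-padding them — fabricated feature values would contaminate
training — and never stack across subject or foot boundaries.

## 5. Classifiers and evaluation

The SVM is a soft-margin RBF-kernel machine trained by sequential
minimal optimisation (C++, deterministic candidate ordering, KKT
tolerance $10^{-3}$); AdaBoost is discrete SAMME with a learning rate
over depth-limited weighted CART trees (gini or entropy). Both are
implemented in the package because no equivalent learner is available
in the supported dependency set; both expose continuous decision scores
(SVM decision value; weighted vote margin) for AUC computation. The
published hyperparameter tables are the shipped defaults per variant;
`tune_hyperparameters()` offers a seeded random search over an inner-CV
AUC objective as an optional re-tuning utility (the original tuning
used Bayesian optimisation, for which no solver is available here — at
equal budget random search explores the same log-uniform space without
adding a dependency).

Decisions:

* **Positive class is FoG throughout**; the operating point for
  sensitivity/specificity is the model's natural boundary (score 0).
* **Standardisation** (z-score, training statistics only) happens
  inside `train_classifier()` and is stored in the model: the published
  RBF bandwidths presuppose comparable feature scales, and per-fold
  standardisation avoids test-set leakage.
* **SVM_5** selects the top-5 base features by chi-square ranking *on
  the training fold* (leakage-free); a fixed feature subset can be
  supplied instead to mimic a global ranking.
* **Labels**: a phase is FoG when its end time lies in an annotated
  episode, interval convention $[{\rm start},{\rm end})$; OR across
  raters for ground truth, AND/OR for the agreement ratio
  (|AND|/|OR|, defined as 1 on an empty OR set).
* **AUC** is the Mann–Whitney statistic (ties one half), computed by
  ranks and verified in the tests against exhaustive pair counting.
* **LOPO-CV** trains on all other subjects' both feet and evaluates the
  held-out subject per foot; degenerate single-class training folds are
  skipped with a warning, never silently.
* The model comparison **t-test is paired** (same subjects under both
  models); a zero-variance difference is reported as a degenerate
  p-value with an explicit flag.
* **Best-foot selection** is the per-subject AUC argmax, ties to the
  left foot with a flag.

## 6. The freezing-index baseline

For each trailing window (default 6 s) the signal is linearly
detrended, Hann-tapered, and the periodogram power summed over the
freeze band $[3,8)$ Hz and the locomotor band $[0.5,3)$ Hz; the index
is their ratio. The locomotor band's lower edge is 0.5 Hz rather than
the nominal 0: including the DC/trend bin makes the index degenerate on
biased accelerometers (`locomotor_lo = 0` restores the literal band).
Band edges are inclusive–exclusive, assigning 3 Hz to the freeze band.
A silent window reports 0; a window with freeze power but vanishing
locomotor power reports `Inf`. The 6-axis vote requires ≥ 4 of 6
per-axis indices above a common threshold (strict majority of six). The
index is scale-invariant by construction and monotone in injected
freeze-band power — both are tested.

## 7. The synthetic generator: what it emulates, what it does not

`simulate_step()` builds a step from closed-form kinematics: pitch
rises along a raised cosine to a heel-off maximum (default 20°), falls
monotonically to a trough (−25°) at 80 % of swing, and recovers to zero
at initial contact, where a 30 ms vertical half-sine transient (8 m/s²)
models the impact — tall enough by construction to trigger D1 in clean
gait. Horizontal displacement follows a minimum-jerk profile (0.6 m
over a 0.7 s swing, zero end velocity), with a small lateral sway and
5 cm of foot lift. Signals are rotated into the sensor frame, gravity
added, and white Gaussian noise applied (0.03 m/s², 0.002 rad/s —
typical consumer-MEMS magnitudes). Defaults reflect the stated world of
the method's target population: 0.7 s average motion phases, strides
well under a metre, 200 Hz sampling.

Subtype morphology: *shuffling* scales pitch to 30 % and stride to
40 %; *festination* uses 0.2 s swings with 0.12 m strides and
inter-step gaps shorter than the rest debounce, so no rest phase
intervenes; *trembling* oscillates the heel at 3–8 Hz (default 5 Hz)
between 0° and 3° with a small, partly vertical acceleration wobble
(vertical so that the acceleration *norm* oscillates at the trembling
frequency rather than its double); *akinesia* is sensor noise only.
Two simulated raters jitter the true episode boundaries by 100 ms SD —
enough to exercise the AND/OR label logic without claiming to match any
particular inter-rater agreement level.

`simulate_cohort()` is deliberately *feature-level*: it draws per-phase
feature rows from class-conditional Gaussians with per-subject baseline
shifts, persistent (Markov) FoG episodes, and a controlled effect size
*d* on the five strongest gait features in their clinically expected
directions (FoG: slower, shorter, flatter). Classifier-recovery
properties (effect recovered at *d* = 2, chance at *d* = 0) are only
meaningful when the effect size is controlled exactly, which a
recording-level simulation cannot do; recording-level realism is
exercised separately through `simulate_recording()` in the segmentation
and feature tests.

A green test on this generator therefore establishes: the state machine
recovers events whose morphology matches its design assumptions; the
strap-down chain is numerically correct; the learners recover known
statistical structure without leaking across subjects. It does **not**
establish clinical performance — real Parkinsonian gait is far more
heterogeneous than the generator, and the published patient-level
results are out of scope without the clinical recordings.

## 8. Known limitations

* The segmentation assumes standing/walking/sitting contexts; other
  activities will produce spurious motion phases.
* Akinesia and start hesitation without any foot motion produce no
  motion phases and are invisible to a motion-phase-centred detector.
* Yaw is unobservable up to drift without a magnetometer; all
  yaw-derived features are phase-relative, and stride length is
  insensitive to heading by construction (tested).
* The complementary filter is a deliberate simplification of the cited
  orientation estimator; any drift-stable accelerometer–gyro fusion
  satisfying the stated contracts (static convergence ≈ 2 s, yaw-free
  correction) is acceptable, and the exact published filter is not
  reproduced.
* The chi-square null calibration, LOPO effect-size recovery and rater
  simulation are stochastic statements under fixed seeds; they
  characterise the stated synthetic world, not clinical data.
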