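---
title: "Modelling energy expenditure during gradient walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling energy expenditure during gradient walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpower)
```

## The model

Walking at speed $v$ on a surface inclined $\theta$ degrees from
horizontal with per-foot stride frequency $f$, a person of mass $M$
expends net (above-basal) metabolic power

$$
P \;=\;
\begin{cases}
\gamma P_K + b_0 P_U + P_0, & \theta \ge 0,\\[4pt]
\gamma P_K + b_0 P_U + b_1 \dfrac{P_U^2}{P_0} + P_0, & \theta < 0,
\end{cases}
$$

with two mechanically derived regressors:

* **Kinetic power** $P_K = 2 M v^2 f$. Each leg is accelerated to a peak
  speed $v_0 = \beta v$ and decelerated again once per stride, so the
  work per cycle is $4 \cdot \tfrac12 m v_0^2 = 2 \alpha \beta^2 M v^2$
  ($m = \alpha M$ is single-leg mass, and the factor 4 counts two legs,
  each accelerating then decelerating). Leg mass, peak leg speed and the
  metabolic-to-kinetic conversion efficiency $\eta_K$ cannot be measured
  by a wearable device, so they are absorbed into the fitted
  dimensionless gain $\gamma = \alpha \beta^2 / \eta_K$, leaving the
  measurable grouping $2 M v^2 f$.
* **Potential power** $P_U = M g v \sin\theta$, the exact rate of change
  of gravitational potential energy; $b_0 = 1/\eta_U$ is the inverse of
  the efficiency with which metabolic energy becomes potential energy.

Uphill the cost is linear in $P_U$. Downhill, a linear model would
predict negative cost on steep declines; in reality braking work grows,
so the model adds a quadratic term $b_1 P_U^2 / P_0$ (divided by $P_0$
to keep $b_1$ dimensionless). Both branches agree at $\theta = 0$
because $P_U(0) = 0$, and the downhill branch has an interior minimum at
$P_U^* = -b_0 P_0 / (2 b_1)$ — around $-8$ to $-12°$ for typical adults
at 2 m/s, consistent with classical reports of a minimum energy cost
near $10°$ downhill. $P_0$ is the constant offset of walking itself
(posture, limb support), not the basal rate, which is subtracted from
the calorimetry before fitting.

Internally all powers are computed in watts and converted at the model
boundary with 1 kcal = 4184 J and $g = 9.80665\,\mathrm{m/s^2}$; since
$\gamma$, $b_0$, $b_1$ are dimensionless this choice cannot affect
predictions (asserted to $10^{-12}$ in the tests). Angles are degrees at
every public interface. The model is calibrated for $|\theta| \le 14°$;
conditions outside that range warn.

### Coefficient interpretation

`reference_coefficients()` carries the published per-sex calibration
(women: $\gamma = 0.662$, $b_0 = 1.591$, $b_1 = 0.575$,
$P_0 = 0.042$ kcal/s; men: $0.517$, $1.694$, $1.086$, $0.058$).
Decomposing $\gamma$ with the anatomical leg-mass fractions
$\alpha = 0.185$ (women) and $0.165$ (men), and assuming
$\eta_K = \eta_U = 1/b_0$, gives
$\beta = \sqrt{\gamma / (\alpha b_0)}$:

```{r}
beta_from_coefficients(0.517, leg_mass_fraction("male"), 1.694)
beta_from_coefficients(0.662, leg_mass_fraction("female"), 1.591)
```

The men's value reproduces the published ratio 1.36 exactly. The
women's evaluates to 1.50, whereas 1.47 was reported from the same
printed inputs (equivalently, $1/b_0 = 0.629$ for women versus the
reported $\eta_U = 0.547$; men agree, $0.590$ vs $0.596$). The printed
women's numbers are not mutually consistent with the printed women's
coefficients under any fixed form of the decomposition we could
identify, so the package reports the formula value and documents the
discrepancy rather than forcing agreement. Only $\beta$'s
interpretation depends on this; predictions use the fitted coefficients
directly.

## Step detection

The insole reports 8 pressure sensors per foot at 10 Hz, each quantised
to 0/1/2. Contact is classified from the per-foot sum with a
dual-threshold hysteresis machine (`contact_states()`): the first frame
is on-ground; from on-ground the foot leaves the ground only when the
sum falls strictly below the lower threshold (default 2); from
off-ground it re-enters only when the sum rises strictly above the
upper threshold (default 5). The strict inequalities follow the
"below"/"above" wording of the protocol; boundary sums hold the state,
and both thresholds are configurable. A single zero threshold fails
when a sensor is stuck at a small positive value; hysteresis with a
lower threshold of 2 tolerates one stuck-at-1 sensor by construction.

A step is an on-ground→off-ground transition; a final unterminated
swing still counts its transition. `step_frequency()` discards the
first 50 s and last 10 s (the calorimetry needs about 30 s to
stabilise, and the same trims are applied to both instruments), counts
transitions whose off-ground frame lies inside the window, divides by
the window duration, and averages the two feet. With a 300 s session
this quantises the frequency to within 1/240 Hz.

## Calorimetry

A portable gas analyzer yields cumulative kilocalories over time.
`gross_rate()` fits an OLS slope over the trimmed window rather than an
endpoint difference, which is robust to sample noise and to the
ramp-in. The basal rate is subtracted to give the net walking power
$P$; the default basal model is the revised Harris–Benedict equation
(per-day kcal / 86 400), chosen because the original protocol cites an
unspecified basal formula — any other can be plugged in via
`basal_model()`, including a measured constant. Negative net rates are
reported with a warning (not clamped by default) so degenerate sessions
remain visible.

## Two-stage calibration

`stage1_fit()` regresses measured net power on $(P_K, P_U)$ with
intercept over flat-and-uphill trials ($\theta \ge 0$), giving
$\gamma$, $b_0$, $P_0$. `stage2_fit()` freezes those and estimates
$b_1$ over flat-and-downhill trials ($\theta \le 0$) in closed form:
with $u = P_U^2/P_0$ and residual $r = P - \gamma P_K - b_0 P_U - P_0$,
$b_1 = \sum r u / \sum u^2$ — the exact single-parameter least-squares
solution (cross-checked against a grid-search minimiser in the tests).
Flat trials have $u = 0$ and carry no weight, so including them is
harmless and mirrors the "flat and downslope" data split.
`fit_by_gender()` runs both stages per sex; trials are pooled across
participants without weighting. Coefficient signs are unconstrained; a
post-fit warning flags negative estimates.

## The synthetic generator

No measurement data accompany the method, so `make_study()` fabricates
complete studies that satisfy the model's assumptions *exactly*: a
recovery failure therefore localises bugs to the processing code.

* **Cohort** (`sample_subjects()`): per-sex truncated normals — heights
  N(161, 6) / N(175, 6) cm, masses N(61, 10) / N(74, 10) kg, ages
  N(43.6, 15) truncated to [20, 60] years — chosen so the pooled moments
  approximate the calibration cohort (168.3 cm, 68.1 kg). The per-sex
  splits are synthetic conventions, not estimates of that cohort.
* **Conditions**: gradients $\{-14,-9,-4,0,4,9,14\}°$ as in the
  treadmill protocol; speeds $\{0.8, 1.1, 1.4, 1.7, 2.0\}$ m/s, a
  choice bracketing normal walking since the protocol's speeds are not
  published; 300 s sessions.
* **Cadence**: inverted from the empirical line $f h = 0.52 v + 1.02$
  (m/s) with Gaussian noise (default SD 0.05 Hz), floored at 0.1 Hz.
* **Observation noise**: each session's true net rate is the model
  prediction plus N(0, 0.016 kcal/s) — the residual scale of the
  original calibration. Rates are floored at $10^{-4}$ kcal/s (the
  calorimetry generator requires a nonnegative rate); the floored value
  is recorded as the ground truth.
* **Pressure traces** (`simulate_pressure_trace()`): a phase model of
  the stride — stance fraction 0.62, heel sensors loading first, then
  midfoot, then toe, mid-stance sum well above the upper threshold,
  swing frames all zero — with the right foot half a cycle out of
  phase, optional stuck sensor, 10 Hz quantisation.
* **Calorimetry** (`simulate_calorimetry()`): rate ramps linearly to
  (net + basal) over 30 s — the reason the default 50 s head trim
  suffices — then integrates with small per-increment noise, clamped
  nondecreasing.

What the generator does **not** emulate: inter-stride variability,
fatigue and drift, breath-by-breath calorimetry artefacts, gait
asymmetries beyond the stuck-sensor mode, and any model mis-specification.
Passing round-trip tests therefore demonstrates correctness of the
pipeline under the model's own assumptions, not accuracy on real
walkers.

## Numerical choices and degenerate inputs

* $\theta = 0$ is assigned to the linear branch; numerically irrelevant
  (branches agree to $10^{-12}$ there) but stated for determinism.
* `stage1_fit()` refuses rank-deficient designs and fewer than 3
  records; `stage2_fit()` requires at least one strictly downhill
  record and errors explicitly when $P_0 \le 0$ or all records are flat.
* Coefficient construction rejects $P_0 \le 0$ (the downhill branch
  divides by $P_0$).
* The hysteresis machine is evaluated as a vectorised
  last-forced-state carry-forward, provably identical to the sequential
  rules; the tests verify the equivalence against a literal recursive
  implementation on 1,000 random sequences.
* All generators are deterministic under a seed and restore the
  caller's RNG state.

## Problem sizes used in validation

The packaged checks run parameter recovery at 1,000 trials per sex
(observation noise 0.016 kcal/s) and a full materialised study of 40
subjects × 7 gradients × 5 speeds (1,400 sessions of 300 s), sizes at
which the whole suite completes in a few minutes on a single core. At
these sizes the stage-1 coefficients recover to within a few percent.
The stage-2 coefficient $b_1$ is the hardest quantity: its single-study
sampling SD is about 7% relative for women (0.575 is a small target,
and errors in the frozen stage-1 estimates propagate into the stage-2
residual through the strong $v^2$ collinearity of $P_K$ and $P_U^2$),
versus about 3% for men. Recovery assertions at a 5% tolerance are
therefore sharp for the women's $b_1$ and can fail for individual
seeds even though the estimator is unbiased (replicate-mean recovery is
well within 5%, which the test suite also asserts).

## Limitations

The model takes no account of load carriage, running gaits, stairs,
surface compliance, or individual gait pathology; it was calibrated on
treadmill walking between ±14° and extrapolation beyond that range is
unvalidated. Per-individual coefficient personalisation is possible in
principle but out of scope — the reference calibration is gender-pooled.
The abstract-level headline accuracies of the original study (RMSD
0.96 kcal/min, median error 12.4%) depend on its unreleased
73-participant dataset and cannot be recomputed here; the package's
validation is parameter recovery on synthetic studies plus the
self-contained worked numbers.
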