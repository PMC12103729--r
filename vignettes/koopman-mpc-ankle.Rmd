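---
title: "Switched Koopman predictors and phase-based MPC for FES ankle assistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switched Koopman predictors and phase-based MPC for FES ankle assistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional electrical stimulation (FES) restores ankle function after
neurological injury by eliciting contractions of the plantarflexors
(gastrocnemius, stance push-off) and dorsiflexors (tibialis anterior, swing
toe clearance).  Designing the stimulation in closed loop is hard because
the FES-actuated ankle is nonlinear (saturating muscle recruitment,
gravitational and joint-stiffness torques) and *switched*: the dynamics
change discretely between the stance and swing phases of the gait cycle,
detected here by thresholding the vertical ground reaction force (GRF).

`koopmanfes` implements the full pipeline at desk scale:

1. a switched nonlinear ankle simulator (`ankle_params()`,
   `simulate_ankle()`);
2. Koopman lifting with observable dictionaries and delay embedding
   (`make_dictionary()`, `lift()`);
3. per-phase extended dynamic mode decomposition (EDMD) yielding a switched
   linear predictor (`fit_koopman()`, `predict_koopman()`);
4. a phase-switched, input-constrained MPC with a discrete algebraic
   Riccati (DARE) terminal cost (`mpc_problem()`, `solve_mpc()`,
   `closed_loop()`);
5. the synthetic-data protocol and study pipelines
   (`generate_dataset()`, `run_prediction_study()`,
   `run_closed_loop_study()`).

## The plant model and its parameters

Per phase $\zeta \in \{P$ (stance), $D$ (swing)$\}$ the ankle obeys

$$J_\zeta \ddot\theta = \tau_{muscle}(u) + (1-\sigma)\, r(\theta)F_{GRF}(t)
  - \big(b\dot\theta + k(\theta - \theta_0) + mgl\sin\theta\big),$$

with $\sigma = 0$ in stance and $1$ in swing.  The torque terms are the
minimal structure containing every named effect — viscous, elastic and
gravitational passive torques, a piecewise-linear saturating recruitment
curve in stimulation current, and a stance-only external torque from a
half-sine GRF template acting on the moment arm
$r(\theta) = r_0\cos\theta$.  Deliberately out of scope: Hill-type fiber
dynamics, activation/fatigue ODEs, and pulse-width/frequency modulation
(current amplitude is the single actuation channel).

Defaults (all exposed in `ankle_params()`, SI units, radians internally,
degrees only at file/report boundaries):

| parameter | default | rationale |
|---|---|---|
| inertia (stance / swing) | 0.02 / 0.01 kg m² | foot segment about the ankle; loaded stance configuration heavier |
| viscous coefficient $b$ | 0.1 N m s/rad | underdamped passive ankle ($\zeta \approx 0.3$) |
| elastic stiffness $k$ | 3 N m/rad | passive joint stiffness; sets ~17 rad/s natural frequency |
| gravity coefficient $mgl$ | 0.8 N m | ~1 kg foot, 0.1 m center of mass |
| recruitment threshold / saturation | 8 / 45 mA | typical transcutaneous motor threshold and saturation |
| maximal muscle torque | 3 N m | makes the ±15° set points reachable inside the 10–25 mA (pf) and 10–20 mA (df) stimulation bounds, checked against the static torque balance |
| GRF peak / moment arm | 300 N / 1 mm | *effective* values: at very slow treadmill speeds the center of pressure stays near the ankle, so the net GRF moment is small compared to muscle torques |
| cycle timing | 1 s, 60 % stance | 200 samples per cycle at 200 Hz |

The sign convention is dorsiflexion positive (the plantarflexor produces
negative torque); there is no universal convention in the field, so it is
fixed here once and used everywhere.

Integration is classical fixed-step RK4 at the sampling rate with
zero-order-hold inputs; the phase flag is frozen over each sample (the
switched discrete-time model) while the GRF clock advances through the RK4
stages.  A `substeps` argument supports step-halving convergence checks.

## Lifting and the switched EDMD predictor

The state used for identification is the 4-dimensional augmented vector
$z = (e_\theta,\ \theta_d,\ e_{\dot\theta},\ \dot\theta_d)$ — tracking
error plus reference.  A 2-dimensional plain joint state
$(\theta, \dot\theta)$ is also supported; see "Controller coordinates"
below.  (A 3-dimensional augmentation with a scalar reference is
expressible through custom term descriptors but has no built-in layout —
the two supported layouts are 4 and 2.)

The `custom` dictionary over the augmented state contains the linear
terms, $\sin/\cos$ of the two position-like coordinates, their squares and
product, and the product of the two velocity-like coordinates — 12
functions, plus a constant observable, giving the lifted dimension
$P = 13$ at embedding length $L = 1$.  The constant term is appended
because standard EDMD practice includes it and it is the only reading
consistent with a 13-dimensional lifting of a 12-function library.  The
identical dictionary object serves both phases, so the stance and swing
operators act on the same lifted space.  Control lifting is the identity
($\Psi_u(u) = u$); delay embedding applies to state observables only.

Per phase, snapshot pairs $(\Psi(x_k, u_k), \Psi(x_{k+1}, u_{k+1}))$ are
collected only where the whole window *and* the successor share the phase
flag — no window straddles a transition (the states are continuous at the
switch, but the vector fields are not).  The operator is the least-squares
solution $\tilde K = F G^{+}$ with
$F = \frac1M\sum D_{k+1}D_k^\top$, $G = \frac1M\sum D_k D_k^\top$; the
rows that would evolve the control observables are fitted and discarded.
A tiny ridge (default $10^{-8}$) stabilizes collinear observables — an
angle and its sine at small angles, and especially adjacent delayed states
at 200 Hz, whose Gram matrices are numerically rank-deficient
(condition numbers beyond $10^{20}$ at $L = 50$).  Without it the
delay-embedded rollouts can diverge.

The recovery map $C$ solves $\min_C \sum \|C\Psi_k - z_k\|^2$ over both
phases pooled (per-phase recovery is available behind a flag).  The
reduced predictor matrices are
$\tilde A_\zeta = C \tilde K^\zeta_{xx} C^{+}$,
$\tilde B_\zeta = C \tilde K^\zeta_{xu}$.  Because $C$ is $n \times P$,
$C^{+}$ must be a *right*-inverse; the package restricts it to the lifted
training subspace by fitting the least-squares pseudo-lift
$E = \Psi Z^{+}$ on the training columns.  The minimum-norm Moore–Penrose
inverse maps states *off* the training manifold (it does not send the
constant observable back to 1) and was observed to introduce spurious
unstable modes into $\tilde A$; the data-restricted right-inverse removes
them while remaining exact on linear systems.

### Rollout paths

`predict_koopman()` offers three multi-step paths:

- **relift** (default): $z_{k+1} = C(\tilde K_{xx}\Psi(z_k\ \text{window})
  + \tilde K_{xu} u_k)$ — the operator is applied on the manifold it was
  trained on at every step.  Most accurate over full gait cycles; used by
  the headline prediction study.
- **lifted**: one lift, then a linear rollout in lifted space.  The
  classical linear predictor; over long horizons it can drift along
  poorly excited lifted directions.
- **reduced**: $z_{k+1} = \tilde A z_k + \tilde B u_k$ — the linear model
  the controller itself uses.

### Evaluation protocols

Two held-out protocols are provided, because delay embedding changes what
is well posed.  The *cycle* protocol anchors on the first $L$ samples of a
held-out cycle and rolls across the whole cycle, switching operators at
the transition; it is the protocol of the headline accuracy number
(threshold: 0.5° angle RMSE, met by the 13-observable custom dictionary).
The *segment* protocol anchors on the first $L$ samples of every
stance/swing segment and predicts to the segment end.  Since training
windows never straddle a transition, the segment protocol is the
well-posed one for $L > 1$ (a cycle-level rollout feeds an $L$-sample
cross-phase window into an operator that never saw one), and it is the
protocol of the embedding-length study, where accuracy improves with
$L = 1 \to 8 \to 50$.

### Identifiability and the excitation modes

The generator's default excitation is the protocol's deterministic
per-phase current ramp (0→30 mA).  Because the identical ramp repeats
every cycle, the input is strongly collinear with the cycle-phase
observables, and the regression can attribute part of the input effect to
the reference coordinates.  That bias is invisible to *prediction* on
held-out cycles generated by the same protocol, but it corrupts the input
matrix $\tilde B$ a controller relies on.  The alternative `random` mode
(per-cycle constant levels drawn from 0–50 mA) decorrelates the input
from cycle phase and identifies $\tilde B$ correctly; it is the mode used
to train controller models.  Both modes are first-class options.

### Controller coordinates

The 4-dimensional augmented model learns the *reference* dynamics from
data.  Its reference-coupling block is identified only on the manifold the
training reference visited — a fixed-amplitude sinusoid traces a
one-dimensional ellipse in $(\theta_d, \dot\theta_d)$ — so a controller
asking it to extrapolate to constant set points operates off-manifold and
under-actuates.  The controller therefore uses a model in absolute joint
coordinates (2-dimensional custom dictionary, $P = 10$): the reference
needs no learned dynamics because the controller knows it exactly, and the
tracking error obeys
$e_{k+1} = \tilde A e_k + (\tilde A x_{d,k} - x_{d,k+1}) + \tilde B u_k$
with the reference entering as a known exogenous signal.  `solve_mpc()`
supports both layouts; the augmented layout remains the default for
identification studies.

## The phase-switched MPC

The receding-horizon problem minimizes

$$\sum_{j=1}^{N-1} e_j^\top Q\, e_j + \sum_{j=0}^{N-1} R\, u_j^2
  + e_N^\top S_\zeta e_N$$

subject to the switched predictor dynamics, the hard stimulation box
(stance: plantarflexor 10–25 mA; swing: dorsiflexor 10–20 mA; one muscle
is decision-active per step, selected by the phase flag), a soft ±20°
state box, and a soft terminal set $e^\top S_\zeta e \le \epsilon$.  The
stage cost deliberately excludes the terminal state so that, with
$S_\zeta$ solving the phase's DARE, the unconstrained problem is the
stationary infinite-horizon regulator — this is what makes consecutive
receding-horizon solutions consistent (the re-solve reproduces the
shifted tail of the previous solution).

Numerical choices, all exposed in `mpc_problem()`:

- **Horizon** 20 steps at 200 Hz (0.1 s), the experimental controller
  setting.
- **Weights** $Q = \mathrm{diag}(100, 1)$ on (angle error, velocity
  error) in radians, $R = 0.01$ per mA².  No numerical weights are
  published for this controller class; these defaults make degree-scale
  errors and the milliamp input range trade off at a few degrees of
  steady-state offset, consistent with the error scale reported for
  FES gait controllers.  They are free parameters.
- **DARE** is solved per phase on the 2-dimensional error subsystem of
  the reduced model by fixed-point iteration of the Riccati recursion
  (symmetrized, relative stagnation tolerance $10^{-13}$); the printed
  terminal weight is 2×2, and the augmented model's reference modes sit
  on the unit circle and are uncontrollable, so no stabilizing
  full-state solution exists — the error subsystem is the right object.
- **Terminal set** level $\epsilon$ defaults to 1; the closed form
  `calibrate_terminal_epsilon()` returns the largest level on which the
  LQR terminal policy respects the input interval
  ($\epsilon_{max} = \Delta u^2 / (K S^{-1} K^\top)$), which is the
  construction that makes the terminal ingredients certify the
  value-function decrease $V_{k+1} \le V_k - \ell(e_k, u_k)$.
- **Solver**: projected spectral (Barzilai–Borwein) gradient on the
  condensed input-only problem with a nonmonotone line search, iteration
  cap 200, tolerance $10^{-8}$ on the projected gradient.  Gradients come
  from the adjoint recursion, so soft penalties are exact.  The solver is
  validated against a dense KKT oracle (unconstrained) and exhaustive
  input-grid search (constrained, short horizons) in the test suite.
- **Soft constraints**: state box and terminal set are quadratic
  penalties (weight 1000); the input box is hard (projection).  Soft
  state constraints guarantee solver feasibility under model mismatch.
- **Fallback**: if a solve errors mid-run, the previous input is held for
  one sample and the event is logged.

`closed_loop()` runs the full loop against the nonlinear simulator:
measure, detect phase from the cycle schedule (the GRF template is zero
at the exact stance boundaries, so schedule-based detection avoids
one-sample chatter at heel strike; thresholded-GRF detection is what
`phase_indicator()` provides for logged data), build the horizon's phase
schedule, solve warm-started, apply the first input to the phase's
muscle.

## The synthetic-data protocol

`generate_dataset()` simulates independent gait cycles: initial angle
uniform in [−20°, 25°], initial velocity uniform in [−2, 2] (read as
rad/s; the printed range carries no units), 200 samples per cycle at
200 Hz, 150 cycles by default (30,000 samples).  The printed initial-angle
interval appears in reversed order in the protocol and is read as
[−20°, 25°].  A sinusoidal reference (10° amplitude, one cycle period) is
attached to every cycle to form the augmented state; within a cycle the
reference pair $(\theta_d, \dot\theta_d)$ is a bijection of cycle time, so
phase-clocked exogenous effects (the GRF template) are partially
learnable from the reference coordinates.  The stance/swing timing is
60/40; the *even split* of training material between phases is restored in
the snapshot assembler, which deterministically thins the larger phase's
pair set to the smaller one's count (`balance = TRUE`).

What the generator does *not* emulate: muscle activation and fatigue
dynamics (no hidden states — the simulated plant is Markovian in the
joint state), measurement noise, trial-to-trial physiological
variability, spasticity, and the kinematic chain above the ankle.
Passing prediction tests on this plant therefore demonstrates the
correctness of the identification and control machinery, not performance
on human data.  One visible consequence: on a Markovian plant, delay
embedding adds information only about the within-segment transient; the
embedding-length improvement here comes from longer anchoring windows,
whereas on real neuromuscular data delays also proxy hidden activation
states.

The closed-loop study maps treadmill speeds to cycle durations
(0.1 m/s → 4 s, 0.2 → 3 s, 0.3 → 2 s, matching the reported 2–4 s cycle
range at those speeds) — an analogy, not a gait reconstruction — and
tracks per-phase set points (−15° plantarflexion in stance, +15°
dorsiflexion in swing, inside the ±20° clearance band) blended with a
0.1 s raised-cosine window so the reference transition is smooth.

## Degenerate inputs and numerical edge cases

- Zero stimulation everywhere below the recruitment threshold; torque is
  continuous and monotone through threshold and saturation kinks.
- All-zero snapshot sets raise a degenerate-fit error; rank-deficient
  lifted Grams warn and solve in regularized form.
- `terminal_check()` accepts boundary states ($e^\top S e = \epsilon$).
- Reference windows that peek beyond the stored reference hold the final
  sample.
- Trajectory validation accepts zero-force stance samples at the exact
  template boundaries (heel strike, toe off); force above the tolerance
  during swing is an error.

## Known limitations

- The reduced linear predictor $(\tilde A, \tilde B)$ is a one-step
  model; its long free rollouts are less accurate than the relift path,
  which is why it is reserved for the (feedback-corrected) controller.
- One muscle per phase: co-stimulation is representable in the simulator
  but not in the controller's decision space.
- No online operator updates, no spectral analysis of $\tilde K$, no
  kernel or learned dictionaries.
- Stability of the switched loop is handled by construction (terminal
  ingredients per phase), not by a formal dwell-time certificate.

## Problem sizes used by the studies

The shipped studies and tests run at desk scale: 30–50 cycles for
identification (the accuracy threshold is already met at 30), three
closed-loop speeds at 2–3 cycles each, and delay embeddings up to
$L = 50$ ($P = 601$).  All randomness flows from a single integer seed;
every report is tagged with the seed and a configuration hash and
regenerates bit-identically.
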