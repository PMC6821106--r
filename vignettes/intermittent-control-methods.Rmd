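---
title: "Methods: continuous versus intermittent control of inaccurately modelled reaches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous versus intermittent control of inaccurately modelled reaches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icreach)
```

## The question the package addresses

Human motor control is commonly modelled as stochastic optimal feedback
control: an observer estimates the limb state from noisy, delayed sensory
measurements, a predictor bridges the delay, and a controller maps the
predicted state to muscle commands. Whether the communication between these
stages is continuous (continuous control, CC) or intermittent (intermittent
control, IC) is an open question. Under periodic IC the predictor runs only
at clock-driven trigger times `t_m = m h`; between triggers a *system-matched
hold* (SMH) propagates the last predicted state in open loop using the
internal model under the known feedback law, `dx_h/dt = (A - B K(t)) x_h`.

For IC to be a plausible account of human control it must tolerate
*inaccurate internal models* — lifting a lighter-than-expected load, moving
in an unfamiliar exoskeleton. `icreach` implements the full apparatus for
that comparison: LQG gain synthesis on the internal model, stability criteria
for CC and periodic IC with and without measurement delay when the true plant
differs from the model, closed-loop simulation of reaching movements, and the
dysmetria (overshoot/undershoot) analysis that connects the simulations to
reaching experiments with ataxia patients and perturbed-inertia exoskeletons.

## Plant and internal model

The forearm and hand are a damped point mass driven by an over-damped
second-order muscle (state `x = [p, p_dot, f, g]`: position relative to the
target, velocity, muscle force, muscle activation):

```
m p'' + gamma p' = f,    mu f' + f = g,    mu g' + g = u + w_g
```

`build_plant()` assembles `A` (upper triangular, spectrum
`{0, -gamma/m, -1/mu, -1/mu}` — the open loop is marginally stable),
`B = [0, 0, 0, 1/mu]'` and `C = [I_2 0]` (only position and velocity are
sensed). Defaults: `mu` = 0.04 s; nominal internal model `m_IM` = 2 kg
(1.5 kg limb + load allowance), `gamma_IM` = 8 N s/m (elbow viscosity mapped
through a 0.3 m forearm). The internal model differs from the plant only in
`m` and `gamma`.

Noise enters the activation state as `w_g/mu`, so the process intensity is
`W = diag(0, 0, 0, (sigma_g/mu)^2)` with `sigma_g` = 0.46 N. The
position/velocity measurement variances `(0.005 m)^2` and `(0.04 m/s)^2` are
*per-frame* variances of a visual channel sampled every 10 ms (their original
estimation context); the continuous-time white-noise intensity that enters
the filter Riccati equation is therefore `V = meas_dt * diag(sigma_p^2,
sigma_v^2)` with `meas_dt` = 0.01 s. This conversion matters: treating the
per-frame variances directly as intensities under-weights the measurements by
two orders of magnitude and washes out every mismatch-induced instability,
whereas with the frame-rate conversion the whole catalogue of published
stability thresholds is reproduced to within 0.03 kg. `noise_scale`
implements the V0 versus V0/10 comparison without a second constructor.

## Gain synthesis

The reach is encoded by a quadratic cost with `Q(t) = 0` during the movement
(`t < T`, `T` = 0.6 s), `Q(t) = Q_inf = diag(1, 0.2^2, 0.02^2, 0)` from `T`
on (right-closed, so `K(t)` is continuous at `T`), `R = 1e-5`, and terminal
weight `S(T) = S_inf(Q_inf, R_inf)` — pinning the finite-horizon design to
the infinite-horizon one so post-`T` corrective gains do not vanish.

* Stationary gains (`lqr_gain_infinite()`, `kalman_gain_infinite()`): no R
  package in the stack provides a continuous algebraic Riccati solver, so
  `solve_care()` implements the Hamiltonian eigenvector method (stable
  invariant subspace of `[[A, -B R^-1 B'], [-Q, -A']]`). Tests verify the
  residual (< 1e-8) and agreement with an independent long-horizon
  integration of the Riccati ODE.
* Time-varying gains (`feedback_schedule()`): the Riccati ODE is integrated
  backward from `S(T) = S_inf` with `deSolve::ode` (lsoda, rtol = atol =
  1e-8) and sampled onto the simulation grid with zero-order hold;
  `K(t > T) = K_inf`. `observer_schedule()` integrates the filter covariance
  forward from `P0` (default: the stationary `P_inf`, i.e. a constant Kalman
  gain; `P0 = 0` is available since the true initial covariance of a reach
  is not knowable from the published account).
* The LTI stability analyses use the infinite-horizon gains — the natural
  reading of "optimized as if the plant is modelled accurately" for a
  time-invariant analysis.

## Stability criteria

All four regimes reduce to an eigenvalue question about a constant matrix
(gains stationary; plant `A_bar, B_bar` possibly different from the model
`A, B` used by observer, predictor and hold):

* **CC, delay-free** — `A_ov = [[A_bar, -B_bar K], [L C, A - BK - LC]]`;
  stable iff the spectral abscissa is negative. For the accurate model the
  spectrum splits into controller and observer parts (separation), which the
  tests assert numerically.
* **IC, delay-free** — the trigger map `x_ov[m+1] = A_p x_ov[m]` with
  `A_p = e^{A_o h}(I - S [0 I])`, `S` solving the Sylvester equation
  `A_o S - S A_F + alpha = 0`, `alpha = e^{-A_o h} B_o K e^{A_F h} - B_o K`.
  The Sylvester solution is the closed form of the inter-sample integral
  `int_0^h e^{-A_o s} B_o K e^{A_F s} ds`.
* **IC, delayed** (`0 < tau < h`) — the map on `[x_ov[m]', x_p[m-1]']'`
  assembled from three Sylvester solutions. The printed form of this result
  in the source literature is typographically damaged, so the implementation
  follows the constructive derivation: split the inter-trigger interval of
  the delayed time base at the trigger, solve each segment in closed form,
  and eliminate the hold state. The block structure that emerges matches the
  printed expression once its undefined symbol is read as `B_o`.
* **CC, delayed** — ZOH discretization at `Delta` (1 ms) of plant, observer
  (`L_d = L Delta`) and predictor, with a `k_tau = tau/Delta` deep shift
  register of past predictions; stable iff all eigenvalues of the
  `(8 + 4 k_tau)`-state matrix `A_ex` lie in the unit circle. `B_d` uses the
  augmented-exponential ZOH integral because the plant matrix is singular.

**Independent oracles.** Each Sylvester-based construction has a second,
independent route implemented alongside it: the delay-free monodromy equals
a sub-block of `exp([[A_o, -B_o K], [0, A_F]] h)` plus the trigger reset;
the delayed monodromy is rebuilt by method of steps with exact per-segment
solves (matrix exponentials of the augmented generators, not Sylvester
equations). Tests require agreement to 1e-8 (delay-free, 20 seeded random
systems plus every parameter set the scans visit) and 1e-6 (delayed). These
tolerances are achievable only with a balanced Pade matrix exponential;
`Matrix::expm` is used throughout (an unbalanced scaling-and-squaring
implementation loses ~6 digits on these stiff non-normal generators).

**Thresholds.** `stability_threshold()` scans `m_PL` over [0.2, 4] kg
(coarse step 0.02 kg; 0.05 kg for the large delayed-CC matrices — the
bisection stage sets the final accuracy either way) and refines the *last*
unstable-to-stable crossing by bisection to 1e-3 kg. The last crossing, not
the first, is the reported threshold: for some internal models the spectral
radius dips below 1 in a narrow low-mass window before re-emerging, and the
quantity of interest is the mass above which the loop stays stable. Sentinels
report bracket-wide stability or instability instead of a number.

## Simulation

`simulate_cc()`/`simulate_ic()` step the full loop on a fixed 1 ms grid.
Every linear flow (plant, observer, predictor, hold) advances by the exact
ZOH discretization of its generator, with the control held constant over each
step; the observer runs on the delayed time base and assimilates `y(t) =
C x(t - tau) + v` through its innovation; the predictor is updated by an
exact O(1) recursion equivalent to re-propagating the delayed estimate
through the buffered controls (`predict_state()` implements the explicit
buffer form, and a test pins the two together through the trigger resets).
Pre-movement history is rest. The first trigger fires at `t = 0`. A
divergence guard truncates runs whose state norm exceeds 1e3.

This consistent-discretization choice has a useful consequence: with noise
off and an accurate model, the hold state reproduces the predictor state
*exactly* (to machine precision) between triggers, for stationary and
time-varying gains alike — the discrete counterpart of the SMH's defining
property, and the reason the accurate-model IC and CC trajectories in the
tests coincide rather than merely resemble each other. It follows that any
CC/IC difference in an accurate-model run must come from noise (innovations
reach IC's hold only at triggers); noise-free sweeps therefore show
identical CC and IC behaviour at the accurate point, and the published
qualitative CC/IC discrepancies there are a noise phenomenon, not a
structural one.

With `noise = TRUE`, process noise is Euler-Maruyama
(`sd = sigma_g/mu * sqrt(dt)`) and measurement noise has per-step variance
`V/dt` (consistent sampling of continuous white noise). Published noisy
trajectories carry unknown seeds, so noisy runs are validated by
stable/unstable classification only (`reach_diverged()`: divergence guard, or
late-time mean deviation exceeding twice the reach amplitude over the final
20% of a 6 s record — long enough that the slowest investigated growth rates
separate cleanly from decay).

## Dysmetria analysis

Following the reaching-dysmetria literature: movement onset = first time
speed exceeds 0.05 m/s; *early velocity* = velocity 0.15 s after onset
(pre-feedback phase); *first correction* = earliest post-peak time at which
velocity drops below 0.01 m/s or reaches a local minimum (5-sample moving
average, strict three-point minima — the window suppresses grid-level
jitter and is configurable); *dysmetria* = position at first correction
minus target, positive = overshoot. The sign convention is fixed here; the
source defines only a difference.

`mismatch_sweep()` repeats the reach (`tau` = 0.15 s, `h` = 0.2 s,
`T` = 0.6 s, time-varying gains) over 9 plant values spanning +-25% of the
internal-model mass or damping ("evenly spaced around" the nominal value,
endpoints included, nominal at the centre) and regresses dysmetria on early
velocity per controller. Sweeps are noise-free by default — the published
sweep figures are smooth single-trial curves and determinism keeps the
acceptance surface exact; a seeded noisy variant is available through the
`cfg` argument. Expected signs: mass sweeps negative (heavier plants start
slower *and* overshoot), damping sweeps positive, under both controllers and
under both the nominal cost and the modified cost
`Q_inf = diag(1, 0.1^2, 0.02^2, 0)`.

## Problem sizes, numerical choices, limitations

* Simulations use `dt` = 1 ms (the discretization the delayed-CC analysis is
  anchored to); sweeps run 1.5 s, classification runs 6 s. `dt` must divide
  `tau` and `h` exactly so triggers and buffers fall on the grid.
* Threshold scans: step 0.02 kg (0.05 kg for delayed CC, whose 408- to
  608-state eigenproblems dominate runtime), bisection to 1e-3 kg.
* Eigenvalue ties need no special handling: the decision statistic is the
  maximum modulus / real part over all eigenvalues.
* The generator emulates the study conditions, not general reaching data:
  additive Gaussian noise (no signal-dependent noise), periodic triggering
  only (no event-driven IC), translational single-joint dynamics without
  stiffness, and measurement delay only (a process delay was reported to
  yield the same stability analysis and is not re-derived). Passing tests
  certify the model world, not human data.
* Stability theory covers stationary gains only; time-varying-gain behaviour
  is assessed by simulation, as in the source analysis.
* One published table cell (internal model 6 kg / 6 N s/m, delayed CC at
  `tau` = 0.15 s) computes to 1.747 kg against a printed 1.80 — just outside
  the 0.05 kg band the other eleven threshold comparisons meet; the
  neighbouring cells and every other regime agree, consistent with a coarser
  scan grid behind that one printed value.
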