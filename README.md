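# icreach

Continuous versus intermittent optimal control of reaching movements with
inaccurate internal models.

## The problem

Optimal-feedback-control accounts of human reaching combine an observer
(state estimation from noisy, delayed position/velocity measurements), a
predictor (bridging the measurement delay) and a feedback controller. In
*continuous control* (CC) these stages communicate at every instant; in
*periodic intermittent control* (IC) the predictor runs only at clock
triggers `t_m = m h`, and between triggers a *system-matched hold* (SMH)
propagates the last prediction in open loop under the known feedback law,
`dx_h/dt = (A - B K(t)) x_h`. IC is attractive as a model of human motor
control (it matches refractory-period phenomena and cuts computation), but
it is only viable if it tolerates an inaccurate internal model — lifting a
lighter load than expected, moving in an exoskeleton.

`icreach` is for computational motor-control researchers who want to
reproduce, probe or extend that comparison. The plant is a muscle-actuated
hand: a damped point mass (`m p'' + gamma p' = f`) driven by an over-damped
second-order muscle (`mu f' + f = g`, `mu g' + g = u + w_g`, `mu` = 40 ms),
with LQG gains synthesized on an internal model whose mass and damping may
differ from the plant's.

The core quantities are closed-loop stability maps. With stationary gains
`K`, `L` and plant (`A_bar`, `B_bar`) differing from the model (`A`, `B`):

* CC, delay-free: `A_ov = [[A_bar, -B_bar K], [L C, A - BK - LC]]`, stable
  iff `max Re(eig) < 0`;
* IC, delay-free: the trigger-to-trigger monodromy
  `A_p = e^{A_o h} (I - S [0 I])`, with `S` solving the Sylvester equation
  `A_o S - S A_F + e^{-A_o h} B_o K e^{A_F h} - B_o K = 0`
  (`A_F = A - BK`), stable iff the spectral radius is below 1;
* IC with measurement delay `tau < h`: a 12-state monodromy on
  `[x_ov[m]', x_p[m-1]']'` built from three Sylvester solutions;
* CC with delay: the ZOH-discretized extended system `A_ex` (state includes
  `tau/Delta` past predictions).

From these, `stability_threshold()` locates the minimum plant mass a given
controller tolerates, `simulate_cc()`/`simulate_ic()` run full reaches
(noise optional, stationary or time-varying Riccati gain schedules), and
`mismatch_sweep()` extracts dysmetria (signed error at the first correction)
versus early velocity (velocity 0.15 s after onset) across plant-mismatch
sweeps — the signature used to compare the models against reaching
experiments with cerebellar patients.

## Worked example

```r
library(icreach)

# LQG design on the nominal internal model (2 kg, 8 N s/m)
design <- lqg_design(m_im = 2, gamma_im = 8)
design
#> stationary LQG design (m_IM = 2 kg, gamma_IM = 8 N s/m, V scale = 1)
#>   K_inf: 316.23 70.925 4.183 2.0604

# How light can the true plant get before delay-free IC at h = 0.1 s
# destabilizes?
stability_threshold(design, "ic_delayfree", h = 0.1)
#> ic_delayfree stability threshold: 0.493 kg

# A delayed intermittent reach with a heavier-than-modelled plant
tr <- simulate_ic(design, plant_params(2.5, 8),
                  sim_config(duration = 1.5, tau = 0.15, h = 0.2))
reach_metrics(tr)
#>   onset_t   early_v first_corr_t first_corr_p  dysmetria          criterion
#> 1   0.066 0.3683613        0.978    0.2137344 0.01373442 velocity_threshold

# Dysmetria vs early velocity across a mass-mismatch sweep
mismatch_sweep("mass", cfg = sim_config(duration = 1.5))
#> mismatch sweep over mass (9 values, m_IM = 2 kg, gamma_IM = 8 N s/m)
#>   cc: dysmetria ~ early velocity slope -0.2566 (r = -0.991)
#>   ic: dysmetria ~ early velocity slope -0.1863 (r = -0.930)
```

Reading the output: the 0.493 kg threshold says IC sampling at 10 Hz
tolerates plants down to a quarter of the modelled mass; a 2.5 kg plant
under a 2 kg model overshoots the 0.2 m target by ~1.4 cm (positive
dysmetria, hypermetria) despite a *slower* early velocity — which is why
the mass sweep's dysmetria/early-velocity slope is negative for both
controllers, the pattern reported in patients with biased internal models
of inertia. A damping sweep flips the sign.

Ready-made experiment runners (`run_experiment()` or the `inst/cli/icreach`
script) regenerate the standard stability curves, threshold tables,
trajectory bundles and sweeps as CSV/JSON with a manifest.

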