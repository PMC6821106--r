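test_that("onset detection on a linear velocity ramp", {
  t <- seq(0, 1, by = 1e-3)
  tr <- synthetic_traj(t, v = t)
  expect_lt(abs(detect_onset(tr) - 0.05), 1.5e-3)
  expect_equal(early_velocity(tr), detect_onset(tr) + 0.15, tolerance = 1e-9)
  expect_error(detect_onset(synthetic_traj(t, v = rep(0, length(t)))),
               "no movement")
  expect_error(early_velocity(synthetic_traj(seq(0, 0.1, 1e-3),
                                             v = seq(0, 0.1, 1e-3))),
               "too short")
})

test_that("first correction fires on the stop threshold for a bell profile", {
  t <- seq(0, 1, by = 1e-3)
  v <- 0.5 * exp(-((t - 0.3) / 0.12)^2)   # single bell reaching ~0
  tr <- synthetic_traj(t, v)
  fc <- first_correction(tr)
  expect_equal(fc$criterion, "velocity_threshold")
  expect_gt(fc$time, 0.3)
  i <- which(t == fc$time)
  expect_lt(v[i], 0.01)
  expect_gt(v[i - 1], 0)
})

test_that("first correction fires on the local minimum for a double bump", {
  t <- seq(0, 1, by = 1e-3)
  v <- 0.4 * exp(-((t - 0.3) / 0.1)^2) + 0.25 * exp(-((t - 0.65) / 0.1)^2) + 0.05
  tr <- synthetic_traj(t, v)
  fc <- first_correction(tr)
  expect_equal(fc$criterion, "local_minimum")
  expect_gt(fc$time, 0.3)
  expect_lt(fc$time, 0.65)
})

test_that("accurate-model reach has near-zero dysmetria and early onset", {
  tr <- simulate_cc(d_nom, cfg = sim_config(duration = 1.5))
  expect_lt(detect_onset(tr), 0.2)
  expect_lt(abs(dysmetria(tr)), 0.01)
})

test_that("mass and damping mismatches push dysmetria in opposite directions", {
  cfg <- sim_config(duration = 1.5)
  for (sim in list(simulate_cc, simulate_ic)) {
    expect_gt(dysmetria(sim(d_nom, plant_params(2.5, 8), cfg)), 0)  # heavier: overshoot
    expect_lt(dysmetria(sim(d_nom, plant_params(1.5, 8), cfg)), 0)  # lighter: undershoot
    expect_gt(dysmetria(sim(d_nom, plant_params(2, 6), cfg)), 0)    # less damped: overshoot
    expect_lt(dysmetria(sim(d_nom, plant_params(2, 10), cfg)), 0)   # more damped: undershoot
  }
})

test_that("early velocity falls as the plant gets heavier", {
  cfg <- sim_config(duration = 1.5)
  ev <- vapply(c(1.5, 2, 2.5), function(m)
    early_velocity(simulate_cc(d_nom, plant_params(m, 8), cfg)), numeric(1))
  expect_true(all(diff(ev) < 0))
})

test_that("dysmetria is smallest for the accurately modelled plant", {
  sw <- mismatch_sweep("mass", values = seq(1.5, 2.5, length.out = 5),
                       cfg = sim_config(duration = 1.5))
  cc <- sw$results[sw$results$mode == "cc", ]
  i_acc <- which(cc$param_value == 2)
  expect_equal(which.min(abs(cc$dysmetria)), i_acc)
})
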