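test_that("predict_state reduces correctly in the degenerate cases", {
  x <- c(0.1, -0.2, 0.3, 0)
  expect_equal(predict_state(x, numeric(0), im_nom$A, im_nom$B, tau = 0), x)
  # no control: homogeneous propagation over the delay
  xp <- predict_state(x, rep(0, 150), im_nom$A, im_nom$B, tau = 0.15)
  expect_equal(xp, as.vector(as.matrix(Matrix::expm(Matrix::Matrix(im_nom$A * 0.15))) %*% x),
               tolerance = 1e-9)
})

test_that("predict_state matches the closed-form ZOH propagation for constant input", {
  x <- c(0.05, 0.1, -0.3, 0.2)
  tau <- 0.1
  u0 <- 0.7
  xp <- predict_state(x, rep(u0, 100), im_nom$A, im_nom$B, tau = tau)
  z <- zoh_discretize(im_nom$A, im_nom$B, tau)   # one exact step over tau
  expect_lt(max(abs(xp - as.vector(z$Ad %*% x + z$Bd * u0))), 1e-9)
  # short history is zero-padded (pre-movement rest)
  xp_pad <- predict_state(x, rep(u0, 40), im_nom$A, im_nom$B, tau = tau)
  xp_ref <- predict_state(x, c(rep(0, 60), rep(u0, 40)), im_nom$A, im_nom$B,
                          tau = tau)
  expect_equal(xp_pad, xp_ref)
})

test_that("the target state is an equilibrium", {
  cfg <- sim_config(duration = 0.8, target = 0, gain_mode = "stationary")
  tr <- simulate_cc(d_nom, cfg = cfg)
  expect_lt(max(abs(tr$p)), 1e-12)
  expect_lt(max(abs(tr$u)), 1e-9)
})

test_that("system-matched hold replicates continuous control exactly for the design model", {
  for (gm in c("stationary", "time_varying")) {
    cfg <- sim_config(duration = 1.2, gain_mode = gm)
    cc <- simulate_cc(d_nom, cfg = cfg)
    ic <- simulate_ic(d_nom, cfg = cfg)
    expect_lt(max(abs(cc$p - ic$p)), 1e-6)
    expect_lt(max(abs(cc$u - ic$u)), 1e-6)
  }
})

test_that("hold state is reset to the predicted state exactly at triggers", {
  plant <- plant_params(1.5, 8)   # mismatched: hold and predictor diverge
  cfg <- sim_config(duration = 1.0, tau = 0.15, h = 0.2)
  tr <- simulate_ic(d_nom, plant, cfg)
  trig <- which(tr$t %% cfg$h < 1e-9)
  expect_gt(length(trig), 3)
  expect_equal(tr$xh_p[trig], tr$xp_p[trig])
  between <- setdiff(seq_len(nrow(tr)), trig)
  expect_gt(max(abs(tr$xh_p[between] - tr$xp_p[between])), 1e-5)
})

test_that("simulated verdicts agree with the spectral stability analysis", {
  # the delay-free and delayed demonstration configurations
  configs <- list(
    list(d = d_nom, mode = "ic", h = 0.1, tau = 0, regime = "ic_delayfree"),
    list(d = d_nom, mode = "ic", h = 0.2, tau = 0, regime = "ic_delayfree"),
    list(d = d_nom, mode = "cc", h = 0.2, tau = 0, regime = "cc_delayfree"),
    list(d = d_low, mode = "cc", h = 0.2, tau = 0, regime = "cc_delayfree"),
    list(d = d_nom, mode = "ic", h = 0.2, tau = 0.15, regime = "ic_delayed"),
    list(d = d_nom, mode = "ic", h = 0.2, tau = 0.1, regime = "ic_delayed"))
  for (cf in configs) {
    spec_stable <- stability_statistic(cf$d, 0.4, cf$regime,
                                       h = cf$h,
                                       tau = if (cf$tau > 0) cf$tau else NULL)$stable
    cfg <- sim_config(duration = 8, tau = cf$tau, h = cf$h,
                      gain_mode = "stationary")
    tr <- if (cf$mode == "cc") simulate_cc(cf$d, plant_params(0.4, 8), cfg)
          else simulate_ic(cf$d, plant_params(0.4, 8), cfg)
    expect_identical(!reach_diverged(tr), spec_stable,
                     label = sprintf("%s h=%g tau=%g", cf$mode, cf$h, cf$tau))
  }
})

test_that("noise-free trajectories converge under step halving", {
  cfg1 <- sim_config(duration = 1.0, dt = 1e-3)
  cfg2 <- sim_config(duration = 1.0, dt = 5e-4)
  tr1 <- simulate_ic(d_nom, plant_params(1.6, 8), cfg1)
  tr2 <- simulate_ic(d_nom, plant_params(1.6, 8), cfg2)
  common <- tr2$t %in% tr1$t
  expect_lt(max(abs(tr1$p - tr2$p[common])), 5e-3)   # O(dt) agreement
})

test_that("noisy runs are reproducible from the seed", {
  cfg <- sim_config(duration = 0.8, noise = TRUE, seed = 7)
  t1 <- simulate_ic(d_nom, plant_params(2.2, 8), cfg)
  t2 <- simulate_ic(d_nom, plant_params(2.2, 8), cfg)
  expect_identical(t1$p, t2$p)
  cfg2 <- sim_config(duration = 0.8, noise = TRUE, seed = 8)
  t3 <- simulate_ic(d_nom, plant_params(2.2, 8), cfg2)
  expect_gt(max(abs(t1$p - t3$p)), 0)
})
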