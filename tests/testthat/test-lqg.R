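test_that("stationary LQR gain stabilizes the design model", {
  fb <- lqr_gain_infinite(im_nom)
  expect_lt(spectral_abscissa(im_nom$A - im_nom$B %*% fb$K), 0)
  # costlier control never increases the gain
  fb2 <- lqr_gain_infinite(im_nom, R_inf = 2e-5)
  expect_lte(sqrt(sum(fb2$K^2)), sqrt(sum(fb$K^2)))
})

test_that("stationary Kalman gain stabilizes the observer", {
  ob <- kalman_gain_infinite(im_nom)
  expect_lt(spectral_abscissa(im_nom$A - ob$L %*% im_nom$C), 0)
  resid <- im_nom$A %*% ob$P + ob$P %*% t(im_nom$A) -
    ob$P %*% t(im_nom$C) %*% solve(im_nom$V) %*% im_nom$C %*% ob$P + im_nom$W
  expect_lt(max(abs(resid)) / max(abs(ob$P %*% t(im_nom$C) %*% solve(im_nom$V) %*% im_nom$C %*% ob$P)), 1e-10)
  # less measurement noise -> smaller stationary estimation covariance
  ob10 <- kalman_gain_infinite(d_low$model)
  expect_lt(sum(diag(ob10$P)), sum(diag(ob$P)))
})

test_that("separation holds for the accurate model under stationary gains", {
  A_ov <- cc_closedloop_delayfree(im_nom$A, im_nom$B, im_nom$A, im_nom$B,
                                  im_nom$C, d_nom$K, d_nom$L)
  expect_lt(spectral_abscissa(A_ov), 0)
  ev <- sort(Re(eigen(A_ov, only.values = TRUE)$values))
  ev_sep <- sort(Re(c(eigen(im_nom$A - im_nom$B %*% d_nom$K)$values,
                      eigen(im_nom$A - d_nom$L %*% im_nom$C)$values)))
  expect_equal(ev, ev_sep, tolerance = 1e-6)
})

test_that("backward feedback schedule meets the stationary gain at T", {
  cost <- build_cost(im_nom)
  grid <- seq(0, 1, by = 1e-3)
  sch <- feedback_schedule(im_nom, cost, grid)
  iT <- which(grid == cost$T)
  expect_equal(as.vector(sch$K[iT, ]), as.vector(d_nom$K), tolerance = 1e-6)
  expect_equal(as.vector(sch$K[length(grid), ]), as.vector(d_nom$K),
               tolerance = 1e-6)
  # continuity at T: the gain just before T is close to K_inf
  expect_equal(as.vector(sch$K[iT - 1, ]), as.vector(d_nom$K),
               tolerance = 1e-2)
  # S(t) symmetric PSD along the backward sweep
  for (i in seq(1, length(grid), by = 100)) {
    S <- sch$S[, , i]
    expect_true(isSymmetric(S, tol = 1e-8))
    expect_gt(min(eigen(S, only.values = TRUE)$values), -1e-8)
  }
})

test_that("a stationary cost keeps the feedback gain constant", {
  cost <- build_cost(im_nom, Q_transient = diag(c(1, 0.2^2, 0.02^2, 0)))
  sch <- feedback_schedule(im_nom, cost, seq(0, 0.8, by = 1e-2))
  for (i in seq_len(nrow(sch$K))) {
    expect_equal(as.vector(sch$K[i, ]), as.vector(d_nom$K), tolerance = 1e-5)
  }
})

test_that("filter covariance schedule is stationary at P_inf and converges", {
  grid <- seq(0, 5, by = 1e-2)
  P_inf <- kalman_gain_infinite(im_nom)$P
  sch <- observer_schedule(im_nom, grid)        # default P0 = P_inf
  expect_equal(sch$L[, , 1], sch$L[, , length(grid)], tolerance = 1e-8)
  expect_equal(sch$L[, , 1], d_nom$L, tolerance = 1e-6)
  sch0 <- observer_schedule(im_nom, grid, P0 = matrix(0, 4, 4))
  traces <- apply(sch0$P, 3, function(P) sum(diag(P)))
  expect_true(all(diff(traces) > -1e-10))       # monotone filling-in
  expect_equal(sch0$P[, , length(grid)], P_inf,
               tolerance = 1e-6 / max(abs(P_inf)))
})
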