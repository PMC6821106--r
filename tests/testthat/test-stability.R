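lemma1_vs_oracle <- function(s, h = s$h) {
  Ap <- ic_monodromy_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, h)
  Ao <- ic_monodromy_oracle_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, h)
  max(abs(Ap - Ao))
}

lemma2_vs_oracle <- function(s, h = s$h, tau = s$tau) {
  At <- ic_monodromy_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, h, tau)
  Ao <- ic_monodromy_oracle_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, h, tau)
  max(abs(At - Ao))
}

paper_system <- function(m_pl, v_scale = 1, gamma_pl = 8) {
  d <- design_for(v_scale)
  pl <- build_plant(plant_params(m_pl, gamma_pl))
  list(Abar = pl$A, Bbar = pl$B, A = d$model$A, B = d$model$B, C = d$model$C,
       K = d$K, L = d$L)
}

test_that("delay-free monodromy without feedback is the open-loop flow", {
  s <- random_system(1)
  s$K <- matrix(0, 1, 4)
  Ao <- rbind(cbind(s$Abar, matrix(0, 4, 4)),
              cbind(s$L %*% s$C, s$A - s$L %*% s$C))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(Ao * s$h)))
  expect_equal(ic_monodromy_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, s$h),
               E, tolerance = 1e-10)
  expect_equal(ic_monodromy_oracle_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C,
                                             s$K, s$L, s$h),
               E, tolerance = 1e-10)
})

test_that("Sylvester and block-exponential routes to the delay-free monodromy agree", {
  for (seed in 1:20) {
    expect_lt(lemma1_vs_oracle(random_system(seed)), 1e-8)
  }
  for (i in seq_len(nrow(paper_delayfree_sets))) {
    s <- paper_system(paper_delayfree_sets$m_pl[i],
                      paper_delayfree_sets$v_scale[i])
    expect_lt(lemma1_vs_oracle(s, h = paper_delayfree_sets$h[i]), 1e-8)
  }
})

test_that("the monodromy tends to the identity as the period shrinks", {
  s <- paper_system(2)
  Ao <- ic_monodromy_oracle_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L,
                                      h = 1e-6)
  expect_lt(max(abs(Ao - diag(8))), 0.05)
  expect_lt(lemma1_vs_oracle(s, h = 1e-6), 1e-8)
})

test_that("heavier-than-modelled plants stay stable under delay-free IC", {
  s <- paper_system(4)
  expect_lt(spectral_radius(
    ic_monodromy_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, 0.1)), 1)
})

test_that("delayed monodromy matches the method-of-steps oracle", {
  for (seed in 1:10) {
    expect_lt(lemma2_vs_oracle(random_system(seed)), 1e-6)
  }
  for (m_pl in c(0.2, 0.4, 2, 4)) {
    for (tau in c(0.1, 0.15)) {
      expect_lt(lemma2_vs_oracle(paper_system(m_pl), h = 0.2, tau = tau), 1e-6)
    }
  }
})

test_that("delayed monodromy is continuous in the delay at tau -> 0", {
  s <- paper_system(0.4)
  Ap <- ic_monodromy_delayfree(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L, h = 0.1)
  gap <- vapply(c(1e-6, 1e-7), function(tau) {
    At <- ic_monodromy_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L,
                               h = 0.1, tau = tau)
    max(abs(At[1:8, 1:8] - Ap))
  }, numeric(1))
  expect_lt(gap[2], 1e-4)
  # first-order convergence: the gap shrinks linearly with the delay
  expect_equal(gap[1] / gap[2], 10, tolerance = 0.05)
})

test_that("delayed constructors reject tau >= h", {
  s <- paper_system(2)
  expect_error(ic_monodromy_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L,
                                    h = 0.1, tau = 0.1), "tau < h")
  expect_error(ic_monodromy_oracle_delayed(s$Abar, s$Bbar, s$A, s$B, s$C,
                                           s$K, s$L, h = 0.1, tau = 0.2),
               "tau < h")
})

test_that("discrete delayed CC matrix decouples with zero gains", {
  s <- paper_system(1.3)
  K0 <- matrix(0, 1, 4); L0 <- matrix(0, 4, 2)
  M <- cc_discrete_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, K0, L0,
                           tau = 1e-3, delta = 1e-3)
  expect_equal(dim(M), c(12, 12))
  ev <- sort(Mod(eigen(M, only.values = TRUE)$values))
  ev_ref <- sort(Mod(c(eigen(zoh_discretize(s$Abar, s$Bbar, 1e-3)$Ad)$values,
                       eigen(zoh_discretize(s$A, s$B, 1e-3)$Ad)$values,
                       rep(0, 4))))
  expect_equal(ev, ev_ref, tolerance = 1e-9)
  expect_error(cc_discrete_delayed(s$Abar, s$Bbar, s$A, s$B, s$C, s$K, s$L,
                                   tau = 0.0015, delta = 1e-3), "integer")
})

test_that("threshold search brackets, bisects and reports sentinels", {
  th <- stability_threshold(d_nom, "ic_delayfree", h = 0.1,
                            bracket = c(0.2, 1), step = 0.1)
  expect_equal(th$sentinel, "none")
  # bisection refines the coarse bracket to the stated resolution
  s_lo <- stability_statistic(d_nom, th$threshold - 2e-3, "ic_delayfree", h = 0.1)
  s_hi <- stability_statistic(d_nom, th$threshold + 1e-4, "ic_delayfree", h = 0.1)
  expect_false(s_lo$stable)
  expect_true(s_hi$stable)
  th_all <- stability_threshold(d_nom, "ic_delayfree", h = 0.2,
                                bracket = c(0.2, 1), step = 0.1)
  expect_equal(th_all$sentinel, "stable_everywhere")
  expect_true(is.na(th_all$threshold))
})
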