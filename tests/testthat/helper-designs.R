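# Shared fixtures: computed once per test run.

d_nom <- lqg_design(2, 8)             # nominal internal model, V = V0
d_low <- lqg_design(2, 8, v_scale = 0.1)   # less noisy measurements, V0/10
im_nom <- d_nom$model

# A random 4-state plant/model/gain set for cross-validating the monodromy
# constructions. Gains are moderate so both construction routes stay well
# conditioned; the plant differs from the model by a random perturbation.
random_system <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(16), 4, 4)
  A <- M - (max(Re(eigen(M, only.values = TRUE)$values)) + 1) * diag(4)
  Abar <- A + 0.3 * matrix(rnorm(16), 4, 4)
  B <- matrix(rnorm(4), 4, 1)
  C <- cbind(diag(2), matrix(0, 2, 2))
  K <- matrix(rnorm(4), 1, 4)
  L <- matrix(0.5 * rnorm(8), 4, 2)
  h <- runif(1, 0.05, 0.3)
  list(Abar = Abar, Bbar = B + 0.2 * matrix(rnorm(4), 4, 1),
       A = A, B = B, C = C, K = K, L = L, h = h,
       tau = h * runif(1, 0.2, 0.8))
}

# The (plant mass, h, v_scale) combinations underlying the delay-free
# stability figures; used to cross-validate Lemma 1 on every set the scans
# visit.
paper_delayfree_sets <- expand.grid(m_pl = c(0.2, 0.4, 1, 2, 4),
                                    h = c(0.05, 0.1, 0.2),
                                    v_scale = c(1, 0.1))

design_for <- function(v_scale) if (v_scale == 1) d_nom else d_low

# Assemble a hand-built reach_trajectory for metric tests.
synthetic_traj <- function(t, v, p = NULL, target = 0.2) {
  if (is.null(p)) p <- cumsum(c(0, diff(t) * (v[-1] + v[-length(v)]) / 2))
  structure(data.frame(t = t, p = p, v = v),
            target = target, mode = "cc", unstable = FALSE,
            class = c("reach_trajectory", "data.frame"))
}
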