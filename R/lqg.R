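#' Infinite-horizon LQR feedback gain
#'
#' Stationary optimal state-feedback gain for the internal model:
#' `K_inf = R^-1 B' S_inf` with `S_inf` the stabilizing solution of the
#' control algebraic Riccati equation. `A - B K_inf` is Hurwitz for the
#' design model.
#'
#' @param model internal [build_plant()] model.
#' @param Q_inf 4 x 4 state weight.
#' @param R_inf scalar control weight.
#' @return list with `K` (1 x 4) and `S` (4 x 4).
#' @export
lqr_gain_infinite <- function(model, Q_inf = diag(c(1, 0.2^2, 0.02^2, 0)),
                              R_inf = 1e-5) {
  stopifnot(inherits(model, "hand_model"))
  S <- solve_care(model$A, model$B, Q_inf, matrix(R_inf))
  K <- solve(matrix(R_inf), t(model$B) %*% S)
  list(K = K, S = S)
}

#' Stationary Kalman (observer) gain
#'
#' Stationary optimal observer gain `L_inf = P_inf C' V^-1` with `P_inf` the
#' stabilizing solution of the filter algebraic Riccati equation
#' `0 = A P + P A' - P C' V^-1 C P + W` (the dual of the control problem).
#' `A - L_inf C` is Hurwitz for the design model.
#'
#' @param model internal [build_plant()] model (supplies `A`, `C`, `W`, `V`).
#' @return list with `L` (4 x 2) and `P` (4 x 4).
#' @export
kalman_gain_infinite <- function(model) {
  stopifnot(inherits(model, "hand_model"))
  P <- solve_care(t(model$A), t(model$C), model$W, model$V)
  L <- P %*% t(model$C) %*% solve(model$V)
  list(L = L, P = P)
}

#' Full stationary LQG design for an internal model
#'
#' Convenience constructor bundling the internal model and its stationary
#' gains, "optimized as if the plant is modelled accurately". This is the
#' design object the stability analyses and LTI simulations consume.
#'
#' @param m_im internal-model mass (kg).
#' @param gamma_im internal-model damping (N s/m).
#' @param v_scale measurement-noise scale (1 for the nominal V0, 0.1 for
#'   V0/10).
#' @param Q_inf,R_inf stationary cost weights.
#' @param mu muscle time constant (s).
#' @param ... further arguments to [build_plant()].
#' @return object of class `lqg_design`: list with `model`, `K`, `S`, `L`,
#'   `P` and the weights.
#' @export
#' @examples
#' d <- lqg_design(2, 8)
#' d$K
lqg_design <- function(m_im, gamma_im, v_scale = 1,
                       Q_inf = diag(c(1, 0.2^2, 0.02^2, 0)), R_inf = 1e-5,
                       mu = 0.04, ...) {
  model <- build_plant(plant_params(m_im, gamma_im, mu),
                       noise_scale = v_scale, ...)
  fb <- lqr_gain_infinite(model, Q_inf, R_inf)
  ob <- kalman_gain_infinite(model)
  structure(list(model = model, K = fb$K, S = fb$S, L = ob$L, P = ob$P,
                 Q_inf = Q_inf, R_inf = R_inf, v_scale = v_scale),
            class = "lqg_design")
}

#' @export
print.lqg_design <- function(x, ...) {
  cat(sprintf("stationary LQG design (m_IM = %g kg, gamma_IM = %g N s/m, V scale = %g)\n",
              x$model$params$m, x$model$params$gamma, x$v_scale))
  cat("  K_inf:", signif(as.vector(x$K), 5), "\n")
  invisible(x)
}

riccati_rhs_control <- function(A, B, Rinv_Bt) {
  force(A); force(B); force(Rinv_Bt)
  function(s, y, parms) {
    S <- matrix(y, 4, 4)
    dS <- t(A) %*% S + S %*% A - (S %*% B) %*% (Rinv_Bt %*% S) + parms$Q(parms$T - s)
    list(as.vector(dS))
  }
}

#' Time-varying feedback gain schedule
#'
#' Integrates the control Riccati differential equation
#' `-dS/dt = A'S + SA - S B R^-1 B' S + Q(t)` backward from
#' `S(T) = S_inf(Q_inf, R_inf)` and returns `K(t) = R^-1 B' S(t)` on a
#' uniform grid. For `t > T` the gain is held at `K(T) = K_inf` (the cost
#' does not constrain it there, but corrections past the intended arrival
#' need non-zero gains). Between grid points the simulator holds the gain
#' constant (zero-order hold).
#'
#' @param model internal model.
#' @param cost a [build_cost()] specification.
#' @param grid time grid (s) covering `[0, T_sim]`; must contain `cost$T`.
#' @param rtol,atol integration tolerances passed to [deSolve::ode()].
#' @return object of class `gain_schedule`: list with `times`, `K`
#'   (length(grid) x 4) and `S` (4 x 4 x length(grid)).
#' @export
feedback_schedule <- function(model, cost, grid, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "hand_model"), inherits(cost, "cost_spec"))
  grid <- sort(grid)
  if (max(grid) < cost$T) {
    stop("time grid must extend at least to the reach time T", call. = FALSE)
  }
  A <- model$A; B <- model$B
  Rinv_Bt <- solve(matrix(cost$R_inf), t(B))
  # backward time s = T - t on [0, T]
  tpre <- grid[grid < cost$T]
  svals <- sort(unique(c(0, cost$T - tpre)))
  sol <- deSolve::ode(y = as.vector(cost$S_T), times = svals,
                      func = riccati_rhs_control(A, B, Rinv_Bt),
                      parms = list(Q = cost$Q, T = cost$T),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("backward Riccati integration failed (stiff step-size breakdown); ",
         "try a finer grid or looser tolerances", call. = FALSE)
  }
  N <- length(grid)
  Karr <- matrix(0, N, 4)
  Sarr <- array(0, c(4, 4, N))
  for (i in seq_len(N)) {
    t <- grid[i]
    S <- if (t >= cost$T) {
      cost$S_T
    } else {
      j <- which.min(abs(svals - (cost$T - t)))
      matrix(sol[j, -1], 4, 4)
    }
    S <- (S + t(S)) / 2
    Sarr[, , i] <- S
    Karr[i, ] <- Rinv_Bt %*% S
  }
  structure(list(times = grid, K = Karr, S = Sarr),
            class = "gain_schedule")
}

riccati_rhs_filter <- function(A, C, W, Vinv) {
  force(A); force(C); force(W); force(Vinv)
  function(t, y, parms) {
    P <- matrix(y, 4, 4)
    dP <- A %*% P + P %*% t(A) - (P %*% t(C)) %*% Vinv %*% (C %*% P) + W
    list(as.vector(dP))
  }
}

#' Time-varying observer (Kalman) gain schedule
#'
#' Integrates the filter Riccati differential equation
#' `dP/dt = A P + P A' - P C' V^-1 C P + W` forward from `P0` and returns
#' `L(t) = P(t) C' V^-1` on the grid. With `P0 = P_inf` the schedule is
#' constant (the stationary filter, the default for simulations); any PSD
#' `P0` converges to `P_inf`.
#'
#' @param model internal model.
#' @param grid time grid (s).
#' @param P0 initial estimation covariance (default: stationary `P_inf`).
#' @param rtol,atol integration tolerances.
#' @return object of class `observer_schedule`: list with `times`, `L`
#'   (4 x 2 x length(grid)) and `P` (4 x 4 x length(grid)).
#' @export
observer_schedule <- function(model, grid, P0 = NULL, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "hand_model"))
  grid <- sort(grid)
  if (is.null(P0)) P0 <- kalman_gain_infinite(model)$P
  if (min(eigen((P0 + t(P0)) / 2, only.values = TRUE)$values) < -1e-10) {
    stop("'P0' must be positive semidefinite", call. = FALSE)
  }
  Vinv <- solve(model$V)
  times <- sort(unique(c(0, grid)))
  sol <- deSolve::ode(y = as.vector(P0), times = times,
                      func = riccati_rhs_filter(model$A, model$C, model$W, Vinv),
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("filter Riccati integration failed", call. = FALSE)
  }
  N <- length(grid)
  Larr <- array(0, c(4, 2, N))
  Parr <- array(0, c(4, 4, N))
  Ct_Vinv <- t(model$C) %*% Vinv
  for (i in seq_len(N)) {
    j <- which.min(abs(times - grid[i]))
    P <- matrix(sol[j, -1], 4, 4)
    P <- (P + t(P)) / 2
    Parr[, , i] <- P
    Larr[, , i] <- P %*% Ct_Vinv
  }
  structure(list(times = grid, L = Larr, P = Parr),
            class = "observer_schedule")
}
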