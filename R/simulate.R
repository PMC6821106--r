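#' Simulation configuration for a reaching movement
#'
#' @param dt integration step (s), default 1e-3. Must divide `tau` and `h`
#'   to machine precision.
#' @param duration simulated time (s); must cover the reach time of the cost
#'   used.
#' @param tau measurement delay (s), >= 0.
#' @param h trigger period of the intermittent controller (s); must exceed
#'   `tau` when `tau > 0`.
#' @param noise logical; draw process and measurement noise. Off by
#'   default: single mismatched reaches are deterministic demonstrations.
#' @param seed integer seed used when `noise = TRUE`.
#' @param target reach amplitude (m); the plant starts `target` metres from
#'   the goal, which is the origin of the regulator coordinates. Reported
#'   positions are shifted so the movement runs from 0 towards `target`.
#' @param gain_mode `"time_varying"` (backward-Riccati schedule, the reach
#'   task) or `"stationary"` (infinite-horizon gains, the LTI stability
#'   demonstrations).
#' @param p0_mode initial estimation covariance of the observer schedule:
#'   `"stationary"` (constant Kalman gain, default) or `"zero"`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, duration = 1.5, tau = 0.15, h = 0.2,
                       noise = FALSE, seed = 1L, target = 0.2,
                       gain_mode = c("time_varying", "stationary"),
                       p0_mode = c("stationary", "zero")) {
  gain_mode <- match.arg(gain_mode)
  p0_mode <- match.arg(p0_mode)
  stopifnot(dt > 0, duration > 0, tau >= 0, h > 0)
  if (tau > 0 && abs(tau / dt - round(tau / dt)) > 1e-8) {
    stop("'dt' must divide 'tau'", call. = FALSE)
  }
  if (abs(h / dt - round(h / dt)) > 1e-8) {
    stop("'dt' must divide 'h'", call. = FALSE)
  }
  if (tau > 0 && tau >= h) {
    stop("intermittent control with delay requires tau < h", call. = FALSE)
  }
  structure(list(dt = dt, duration = duration, tau = tau, h = h,
                 noise = noise, seed = as.integer(seed), target = target,
                 gain_mode = gain_mode, p0_mode = p0_mode),
            class = "sim_config")
}

#' Predict the current state from a delayed estimate
#'
#' Forward-propagates the delayed state estimate through the internal model
#' over the delay interval, adding the effect of the controls already
#' issued: `x_p(t) = e^{A tau} x_hat(t - tau) + int e^{A (t - s)} B u(s) ds`.
#' The control history is piecewise constant at the simulation step, so each
#' substep is an exact zero-order-hold propagation.
#'
#' @param x_hat_delayed length-4 delayed estimate `x_hat(t - tau)`.
#' @param u_history controls on `[t - tau, t)`, oldest first, one per `dt`
#'   substep (`tau/dt` values). A shorter history (movement onset) is
#'   zero-padded on the left: the system is at rest before the reach.
#' @param A,B internal-model matrices.
#' @param tau delay (s); `0` returns the estimate unchanged.
#' @param dt substep (s).
#' @return length-4 predicted state `x_p(t)`.
#' @export
predict_state <- function(x_hat_delayed, u_history, A, B, tau, dt = 1e-3) {
  if (tau == 0) return(as.numeric(x_hat_delayed))
  kt <- round(tau / dt)
  if (abs(tau / dt - kt) > 1e-8) stop("'dt' must divide 'tau'", call. = FALSE)
  if (length(u_history) > kt) {
    stop("control history longer than the delay window", call. = FALSE)
  }
  u <- c(rep(0, kt - length(u_history)), u_history)
  z <- zoh_discretize(A, B, dt)
  x <- as.numeric(x_hat_delayed)
  for (i in seq_len(kt)) x <- as.vector(z$Ad %*% x + z$Bd * u[i])
  x
}

# Resolve the time-varying (or constant) gain matrices on the simulation
# grid. Returns K as (N+1) x 4 and L as 4 x 2 x (N+1).
resolve_gains <- function(design, cost, cfg) {
  N <- round(cfg$duration / cfg$dt)
  grid <- seq(0, by = cfg$dt, length.out = N + 1)
  if (cfg$gain_mode == "stationary") {
    Kt <- matrix(rep(as.vector(design$K), N + 1), N + 1, 4, byrow = TRUE)
  } else {
    if (is.null(cost)) cost <- build_cost(design$model, Q_inf = design$Q_inf,
                                          R_inf = design$R_inf)
    if (cfg$duration < cost$T) {
      stop("simulation duration must cover the reach time T", call. = FALSE)
    }
    Kt <- feedback_schedule(design$model, cost, grid)$K
  }
  if (cfg$p0_mode == "stationary") {
    Lt <- array(rep(as.vector(design$L), N + 1), c(4, 2, N + 1))
  } else {
    Lt <- observer_schedule(design$model, grid, P0 = matrix(0, 4, 4))$L
  }
  list(K = Kt, L = Lt, grid = grid)
}

#' @name simulate_reach
#' @title Simulate a reaching movement under continuous or intermittent
#'   control
#'
#' @description
#' Steps the full observer-predictor-feedback loop on a fixed grid. All
#' linear flows (true plant, observer, predictor, hold) advance by exact
#' zero-order-hold discretization of their generators at `dt`, so with noise
#' off, an accurate model and a consistent gain schedule the intermittent
#' hold replicates the continuous predictor exactly between triggers — the
#' defining property of the system-matched hold.
#'
#' Loop structure per step: the control is computed from the predictor state
#' (CC) or hold state (IC, reset to the predicted state at each trigger
#' `t_m = m h`, first trigger at t = 0); the measurement `y(t) = C x(t-tau)
#' + v` is then assimilated by the observer, which runs on the delayed time
#' base with the delayed control `u(t - tau)`; the predictor is advanced
#' incrementally (equivalent to re-propagating the delayed estimate through
#' the buffered controls). Pre-movement history is rest: `x(s) = x0`,
#' `u(s) = 0` for `s < 0`.
#'
#' With `noise = TRUE`, the process noise is Euler-Maruyama
#' (`sd = sigma_g/mu * sqrt(dt)` on the activation state) and the
#' measurement noise has per-step variance `V/dt` (continuous intensity `V`
#' sampled at `dt`).
#'
#' A divergence guard truncates the run and flags it unstable once the state
#' norm exceeds 1e3.
#'
#' @param design an [lqg_design()] built on the internal model.
#' @param plant the true plant: a [build_plant()] model, a [plant_params()]
#'   object, or `NULL` for an accurately modelled plant.
#' @param cfg a [sim_config()].
#' @param cost a [build_cost()] specification for time-varying gains
#'   (defaults to the nominal reach cost of the design).
#' @return a `reach_trajectory`: data.frame with columns `t`, `p`, `v`, `f`,
#'   `g` (true state; positions shifted so the target sits at
#'   `cfg$target`), `p_hat`, `v_hat` (delayed estimate), `u`, `xp_p`,
#'   `xp_v` (predictor) and, for intermittent control, `xh_p`, `xh_v`
#'   (hold state). Attributes: `target`, `mode`, `unstable`, `cfg`.
#' @examples
#' d <- lqg_design(2, 8)
#' tr <- simulate_cc(d, cfg = sim_config(duration = 1, tau = 0.05))
#' tail(tr$p, 1)  # ~0.2 m
NULL

#' @rdname simulate_reach
#' @export
simulate_cc <- function(design, plant = NULL, cfg = sim_config(), cost = NULL) {
  simulate_reach_core(design, plant, cfg, cost, mode = "cc")
}

#' @rdname simulate_reach
#' @export
simulate_ic <- function(design, plant = NULL, cfg = sim_config(), cost = NULL) {
  simulate_reach_core(design, plant, cfg, cost, mode = "ic")
}

simulate_reach_core <- function(design, plant, cfg, cost, mode) {
  stopifnot(inherits(design, "lqg_design"), inherits(cfg, "sim_config"))
  if (is.null(plant)) plant <- design$model
  if (inherits(plant, "plant_params")) plant <- build_plant(plant)
  stopifnot(inherits(plant, "hand_model"))

  im <- design$model
  dt <- cfg$dt
  N <- round(cfg$duration / dt)
  kt <- round(cfg$tau / dt)
  hsteps <- round(cfg$h / dt)
  g <- resolve_gains(design, cost, cfg)
  Kt <- g$K
  Lt <- g$L

  zi <- zoh_discretize(im$A, im$B, dt)
  zp <- zoh_discretize(plant$A, plant$B, dt)
  Gd <- zoh_discretize(im$A, diag(4), dt)$Bd       # int_0^dt e^{A s} ds
  Phi_tau <- if (kt > 0) expm_mat(im$A * cfg$tau) else diag(4)

  x0 <- c(-cfg$target, 0, 0, 0)                    # target at the origin
  x <- x0
  xhd <- x0                                        # x_hat(t - tau)
  xp <- as.vector(Phi_tau %*% xhd)                 # = x0 (rest equilibrium)
  xh <- xp
  xbuf <- matrix(x0, 4, kt + 1)                    # x(t-tau) ... x(t)
  ubuf <- rep(0, max(kt, 1))
  if (cfg$noise) set.seed(cfg$seed)
  sd_w <- plant$noise$sigma_g / plant$params$mu * sqrt(dt)
  sd_v <- sqrt(diag(im$V) / dt)

  cols <- 10L + if (mode == "ic") 2L else 0L
  out <- matrix(NA_real_, N + 1, cols)
  unstable <- FALSE
  for (k in 0:N) {
    Kk <- Kt[k + 1, ]
    Lk <- Lt[, , k + 1]
    if (mode == "ic" && k %% hsteps == 0) xh <- xp
    u <- if (mode == "cc") -sum(Kk * xp) else -sum(Kk * xh)
    out[k + 1, 1:10] <- c(k * dt, x, xhd[1:2], u, xp[1:2])
    if (mode == "ic") out[k + 1, 11:12] <- xh[1:2]
    if (k == N) break
    if (max(abs(x)) > 1e3) {
      unstable <- TRUE
      break
    }
    xdel <- if (kt > 0) xbuf[, 1] else x
    vmeas <- if (cfg$noise) stats::rnorm(2, 0, sd_v) else c(0, 0)
    y <- as.vector(im$C %*% xdel) + vmeas
    udel <- if (kt > 0) ubuf[1] else u
    innov <- y - as.vector(im$C %*% xhd)
    GLnu <- as.vector(Gd %*% (Lk %*% innov))
    xhd_new <- as.vector(zi$Ad %*% xhd + zi$Bd * udel) + GLnu
    xp <- as.vector(zi$Ad %*% xp + zi$Bd * u) + as.vector(Phi_tau %*% GLnu)
    if (mode == "ic") xh <- as.vector(zi$Ad %*% xh + zi$Bd * u)
    w <- if (cfg$noise) c(0, 0, 0, sd_w * stats::rnorm(1)) else 0
    x <- as.vector(zp$Ad %*% x + zp$Bd * u) + w
    if (kt > 0) {
      xbuf <- cbind(xbuf[, -1, drop = FALSE], x)
      ubuf <- c(ubuf[-1], u)
    }
    xhd <- xhd_new
  }

  keep <- !is.na(out[, 1])
  df <- as.data.frame(out[keep, , drop = FALSE])
  names(df) <- c("t", "p", "v", "f", "g", "p_hat", "v_hat", "u",
                 "xp_p", "xp_v", if (mode == "ic") c("xh_p", "xh_v"))
  # shift positions so the reach runs from 0 towards +target
  for (colp in intersect(c("p", "p_hat", "xp_p", "xh_p"), names(df))) {
    df[[colp]] <- df[[colp]] + cfg$target
  }
  structure(df, target = cfg$target, mode = mode, unstable = unstable,
            cfg = cfg, class = c("reach_trajectory", "data.frame"))
}

#' Did a simulated reach diverge?
#'
#' A run is classed unstable if the divergence guard tripped during the
#' simulation or the peak position deviation from the target over the late
#' part of the record exceeds twice the reach amplitude (slowly growing
#' oscillations that have not yet hit the hard guard). Records should be
#' long enough for the slowest growth rate of interest to separate from
#' decay; 8 s covers the demonstration cases.
#'
#' @param traj a `reach_trajectory`.
#' @param late_frac fraction of the record treated as "late" (default 0.2).
#' @return logical.
#' @export
reach_diverged <- function(traj, late_frac = 0.2) {
  stopifnot(inherits(traj, "reach_trajectory"))
  if (attr(traj, "unstable")) return(TRUE)
  target <- attr(traj, "target")
  n <- nrow(traj)
  late <- traj$p[max(1, floor((1 - late_frac) * n)):n]
  max(abs(late - target)) > 2 * target
}
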