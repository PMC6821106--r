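#' Physical parameters of the hand plant or its internal model
#'
#' The forearm and hand (plus any grasped load or manipulandum) are modelled
#' as a damped point mass driven by an over-damped second-order muscle.
#' Elbow rotation is approximated by a translational movement, and stiffness
#' is omitted: inertia and damping dominate the behaviour of interest.
#'
#' @param m mass (kg), > 0. The bare forearm and hand are about 1.5 kg;
#'   internal-model values of 2-6 kg account for loads.
#' @param gamma translational damping (N s/m), >= 0. The nominal 8 N s/m
#'   corresponds to angular elbow damping of ~0.7 N m s/rad over a 0.3 m
#'   forearm.
#' @param mu muscle time constant (s), > 0; both first-order muscle stages
#'   share the default 0.04 s.
#' @return an object of class `plant_params`.
#' @export
#' @examples
#' plant_params(2, 8)
plant_params <- function(m, gamma, mu = 0.04) {
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0) {
    stop("mass 'm' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma < 0) {
    stop("damping 'gamma' must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu <= 0) {
    stop("muscle time constant 'mu' must be a positive number", call. = FALSE)
  }
  structure(list(m = m, gamma = gamma, mu = mu), class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat(sprintf("hand plant parameters: m = %g kg, gamma = %g N s/m, mu = %g s\n",
              x$m, x$gamma, x$mu))
  invisible(x)
}

#' Build the state-space hand model
#'
#' Assembles the four-state linear model of the muscle-actuated hand. The
#' state is `x = [p, p_dot, f, g]`: hand position relative to the target (m),
#' velocity (m/s), muscle force (N) and the internal muscle activation state
#' (N). Dynamics:
#' \deqn{m \ddot p + \gamma \dot p = f, \quad
#'       \mu \dot f + f = g, \quad \mu \dot g + g = u + w_g,}
#' giving an upper-triangular `A` with spectrum `{0, -gamma/m, -1/mu, -1/mu}`
#' (the open-loop plant is marginally stable), `B = [0, 0, 0, 1/mu]'`, and
#' `C = [I_2 0]`: only position and velocity are sensed.
#'
#' Noise: the process noise enters the activation state as `w_g/mu`, so
#' `W = diag(0, 0, 0, (sigma_g/mu)^2)`. The position/velocity measurement
#' variances `sigma_p^2`, `sigma_v^2` are per-sample values of a visual
#' channel delivering frames every `meas_dt`; the equivalent continuous
#' white-noise intensity used for Kalman-gain synthesis is
#' `V = noise_scale * meas_dt * diag(sigma_p^2, sigma_v^2)`.
#'
#' @param params a [plant_params()] object (or a mass, in which case `gamma`
#'   and `mu` must be supplied via `...` through [plant_params()]).
#' @param sigma_g process-noise standard deviation (N), default 0.46.
#' @param sigma_p position measurement standard deviation (m), default 0.005.
#' @param sigma_v velocity measurement standard deviation (m/s), default 0.04.
#' @param noise_scale multiplies the measurement covariance; `0.1` gives the
#'   "less noisy measurements" variant V0/10.
#' @param meas_dt sensory frame interval (s) converting per-sample variances
#'   to a continuous intensity; default 0.01.
#' @return an object of class `hand_model`: list with `A`, `B`, `C`, `W`,
#'   `V`, and the `params`/noise settings used.
#' @export
#' @examples
#' mod <- build_plant(plant_params(2, 8))
#' mod$A
build_plant <- function(params, sigma_g = 0.46, sigma_p = 0.005,
                        sigma_v = 0.04, noise_scale = 1, meas_dt = 0.01) {
  if (!inherits(params, "plant_params")) {
    stop("'params' must be a plant_params object", call. = FALSE)
  }
  if (!is.numeric(noise_scale) || noise_scale <= 0) {
    stop("'noise_scale' must be positive", call. = FALSE)
  }
  m <- params$m; gam <- params$gamma; mu <- params$mu
  A <- matrix(c(0, 1, 0, 0,
                0, -gam / m, 1 / m, 0,
                0, 0, -1 / mu, 1 / mu,
                0, 0, 0, -1 / mu), 4, 4, byrow = TRUE)
  B <- matrix(c(0, 0, 0, 1 / mu), 4, 1)
  C <- cbind(diag(2), matrix(0, 2, 2))
  W <- diag(c(0, 0, 0, (sigma_g / mu)^2))
  V <- noise_scale * meas_dt * diag(c(sigma_p^2, sigma_v^2))
  structure(list(A = A, B = B, C = C, W = W, V = V,
                 params = params,
                 noise = list(sigma_g = sigma_g, sigma_p = sigma_p,
                              sigma_v = sigma_v, noise_scale = noise_scale,
                              meas_dt = meas_dt)),
            class = "hand_model")
}

#' @export
print.hand_model <- function(x, ...) {
  cat("4-state muscle-actuated hand model\n")
  print(x$params)
  cat(sprintf("  noise: sigma_g = %g N, V scale = %g\n",
              x$noise$sigma_g, x$noise$noise_scale))
  invisible(x)
}

#' Quadratic cost specification for a timed reach
#'
#' The reach is encoded as a quadratic cost
#' \deqn{J = E[x'(T) S(T) x(T) + \int_0^T x' Q(t) x + u' R u \; dt]}
#' with the origin redefined as the target state. Deviations are free during
#' the movement (`Q(t) = 0` for `t < T`) and penalized from the intended
#' arrival time on (`Q(t) = Q_inf` for `t >= T`; the boundary is closed on
#' the right so the feedback gain is continuous at `T`). The terminal weight
#' is pinned to the stationary Riccati solution,
#' `S(T) = S_inf(Q_inf, R_inf)`, which makes the finite-horizon design the
#' restriction of an infinite-horizon one and keeps the post-`T` gains
#' non-vanishing.
#'
#' @param model the internal [build_plant()] model the gains are designed on.
#' @param T intended reach duration (s), default 0.6.
#' @param Q_inf 4 x 4 stationary state weight, default
#'   `diag(1, 0.2^2, 0.02^2, 0)` (position errors dominate; velocity and
#'   force must also settle).
#' @param R_inf control-effort weight (scalar), default `1e-5`.
#' @param Q_transient optional 4 x 4 weight used for `t < T` instead of zero.
#' @return object of class `cost_spec`: list with `T`, `Q_inf`, `R_inf`,
#'   `S_T` (= `S_inf`) and the weight function `Q(t)`.
#' @export
build_cost <- function(model, T = 0.6,
                       Q_inf = diag(c(1, 0.2^2, 0.02^2, 0)),
                       R_inf = 1e-5, Q_transient = NULL) {
  stopifnot(inherits(model, "hand_model"), T > 0, R_inf > 0)
  if (min(eigen(Q_inf, only.values = TRUE)$values) < -1e-12) {
    stop("'Q_inf' must be positive semidefinite", call. = FALSE)
  }
  S_T <- solve_care(model$A, model$B, Q_inf, matrix(R_inf))
  Qt <- if (is.null(Q_transient)) matrix(0, 4, 4) else Q_transient
  Qfun <- function(t) if (t >= T) Q_inf else Qt
  structure(list(T = T, Q_inf = Q_inf, R_inf = R_inf, S_T = S_T, Q = Qfun,
                 Q_transient = Qt),
            class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("reach cost: T = %g s, R_inf = %g, diag(Q_inf) = [%s]\n",
              x$T, x$R_inf, paste(diag(x$Q_inf), collapse = ", ")))
  invisible(x)
}
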