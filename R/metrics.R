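#' Movement onset time
#'
#' First grid time at which the hand speed exceeds the onset threshold.
#'
#' @param traj a `reach_trajectory`.
#' @param threshold onset speed (m/s), default 0.05.
#' @return onset time (s).
#' @export
detect_onset <- function(traj, threshold = 0.05) {
  stopifnot(inherits(traj, "reach_trajectory"))
  i <- which(traj$v > threshold)[1]
  if (is.na(i)) {
    stop("no movement: velocity never exceeds the onset threshold",
         call. = FALSE)
  }
  traj$t[i]
}

#' Early velocity of a reach
#'
#' Hand velocity a fixed interval after movement onset; a proxy for the
#' preplanned, feedback-free phase of the movement.
#'
#' @param traj a `reach_trajectory`.
#' @param offset interval after onset (s), default 0.15.
#' @param onset_threshold onset speed (m/s).
#' @return velocity (m/s).
#' @export
early_velocity <- function(traj, offset = 0.15, onset_threshold = 0.05) {
  t_on <- detect_onset(traj, onset_threshold)
  t_ev <- t_on + offset
  if (t_ev > max(traj$t)) {
    stop("trajectory too short: no sample ", offset, " s after onset",
         call. = FALSE)
  }
  stats::approx(traj$t, traj$v, xout = t_ev)$y
}

#' Time and position of the first correction
#'
#' The first correction ends the preplanned phase of the reach: the earliest
#' time after the velocity peak at which either the velocity drops below a
#' threshold (movement effectively stops) or the velocity reaches a local
#' minimum (a corrective sub-movement begins). Local minima are detected on
#' a moving-average-smoothed velocity with strict inequalities over three
#' consecutive samples, suppressing grid-level jitter.
#'
#' @param traj a `reach_trajectory`.
#' @param v_threshold stop threshold (m/s), default 0.01.
#' @param smooth_window moving-average window (samples) for the
#'   local-minimum search, default 5.
#' @param onset_threshold onset speed (m/s).
#' @return list with `time` (s), `position` (m), and `criterion`
#'   (`"velocity_threshold"`, `"local_minimum"`, or `"end_of_record"` when
#'   neither event occurs before the record ends).
#' @export
first_correction <- function(traj, v_threshold = 0.01, smooth_window = 5,
                             onset_threshold = 0.05) {
  stopifnot(inherits(traj, "reach_trajectory"))
  t_on <- detect_onset(traj, onset_threshold)
  v <- traj$v
  vs <- as.numeric(stats::filter(v, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  i_on <- which(traj$t >= t_on)[1]
  i_pk <- which.max(vs[i_on:length(vs)]) + i_on - 1
  n <- length(v)
  for (j in (i_pk + 1):(n - 1)) {
    if (v[j] < v_threshold) {
      return(list(time = traj$t[j], position = traj$p[j],
                  criterion = "velocity_threshold"))
    }
    if (vs[j] < vs[j - 1] && vs[j] < vs[j + 1]) {
      return(list(time = traj$t[j], position = traj$p[j],
                  criterion = "local_minimum"))
    }
  }
  warning("no first-correction event before the end of the record",
          call. = FALSE)
  list(time = traj$t[n], position = traj$p[n], criterion = "end_of_record")
}

#' Dysmetria of a simulated reach
#'
#' Signed reach error at the first correction: position at the first
#' correction minus target position. Positive values are overshoot
#' (hypermetria), negative undershoot (hypometria).
#'
#' @param traj a `reach_trajectory`.
#' @param ... passed to [first_correction()].
#' @return dysmetria (m).
#' @export
dysmetria <- function(traj, ...) {
  fc <- first_correction(traj, ...)
  fc$position - attr(traj, "target")
}

#' All reach metrics of one trajectory
#'
#' @param traj a `reach_trajectory`.
#' @param ... passed to the individual metric functions.
#' @return one-row data.frame: `onset_t`, `early_v`, `first_corr_t`,
#'   `first_corr_p`, `dysmetria`, `criterion`.
#' @export
reach_metrics <- function(traj, ...) {
  t_on <- detect_onset(traj)
  ev <- early_velocity(traj)
  fc <- first_correction(traj, ...)
  data.frame(onset_t = t_on, early_v = ev, first_corr_t = fc$time,
             first_corr_p = fc$position,
             dysmetria = fc$position - attr(traj, "target"),
             criterion = fc$criterion)
}

#' Dysmetria versus early velocity across a plant-mismatch sweep
#'
#' Repeats a delayed reaching simulation over a set of true plant masses or
#' dampings while the internal model (and hence the controller) stays fixed,
#' under both continuous and periodic intermittent control, and regresses
#' dysmetria on early velocity per controller. With inaccurately modelled
#' mass the two are negatively correlated; with inaccurately modelled
#' damping, positively.
#'
#' Sweeps are noise-free by default, making the metrics deterministic; the
#' swept values default to 9 points spanning +-25% of the internal-model
#' value. Runs that diverge are excluded from the regression (with a
#' warning) and flagged in the output.
#'
#' @param vary `"mass"` or `"damping"`.
#' @param m_im,gamma_im internal-model mass (kg) and damping (N s/m).
#' @param values swept plant values; default
#'   `seq(0.75, 1.25, length.out = n) * nominal`.
#' @param n number of sweep points when `values` is NULL.
#' @param modes controllers to run (`"cc"`, `"ic"`).
#' @param Q_inf stationary state weight of the cost (the modified cost
#'   `diag(1, 0.1^2, 0.02^2, 0)` relaxes the late velocity penalty).
#' @param cfg a [sim_config()]; defaults to the reach task (`tau` 0.15 s,
#'   `h` 0.2 s, time-varying gains, noise off).
#' @param ... passed to [lqg_design()].
#' @return object of class `mismatch_sweep`: list with `results` (one row
#'   per run: `param_value`, `mode`, metrics, `excluded`), `fits` (per-mode
#'   `lm` objects of dysmetria ~ early velocity), `slopes`, and the sweep
#'   description.
#' @export
#' @examples
#' \donttest{
#' sw <- mismatch_sweep("mass", cfg = sim_config(duration = 1.2))
#' sw$slopes  # negative for both controllers
#' }
mismatch_sweep <- function(vary = c("mass", "damping"), m_im = 2,
                           gamma_im = 8, values = NULL, n = 9,
                           modes = c("cc", "ic"),
                           Q_inf = diag(c(1, 0.2^2, 0.02^2, 0)),
                           cfg = sim_config(), ...) {
  vary <- match.arg(vary)
  nominal <- if (vary == "mass") m_im else gamma_im
  if (is.null(values)) values <- seq(0.75, 1.25, length.out = n) * nominal
  design <- lqg_design(m_im, gamma_im, Q_inf = Q_inf, ...)
  cost <- build_cost(design$model, Q_inf = Q_inf, R_inf = design$R_inf)
  # gain schedule depends only on the internal model: compute once
  gains_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (val in values) {
    plant <- if (vary == "mass") plant_params(val, gamma_im)
             else plant_params(m_im, val)
    for (mode in modes) {
      traj <- if (mode == "cc") simulate_cc(design, plant, cfg, cost)
              else simulate_ic(design, plant, cfg, cost)
      excluded <- reach_diverged(traj)
      met <- if (excluded) {
        data.frame(onset_t = NA_real_, early_v = NA_real_,
                   first_corr_t = NA_real_, first_corr_p = NA_real_,
                   dysmetria = NA_real_, criterion = "diverged")
      } else {
        reach_metrics(traj)
      }
      rows[[length(rows) + 1]] <- cbind(data.frame(param_value = val,
                                                   mode = mode), met,
                                        data.frame(excluded = excluded))
    }
  }
  results <- do.call(rbind, rows)
  if (any(results$excluded)) {
    warning(sum(results$excluded), " unstable run(s) excluded from the ",
            "regression", call. = FALSE)
  }
  fits <- lapply(stats::setNames(modes, modes), function(mode) {
    sub <- results[results$mode == mode & !results$excluded, ]
    stats::lm(dysmetria ~ early_v, data = sub)
  })
  slopes <- vapply(fits, function(f) unname(stats::coef(f)[2]), numeric(1))
  rvals <- vapply(fits, function(f) {
    s <- summary(f)
    sign(stats::coef(f)[2]) * sqrt(s$r.squared)
  }, numeric(1))
  structure(list(results = results, fits = fits, slopes = slopes, r = rvals,
                 vary = vary, m_im = m_im, gamma_im = gamma_im,
                 Q_inf = Q_inf, values = values),
            class = "mismatch_sweep")
}

#' @export
print.mismatch_sweep <- function(x, ...) {
  cat(sprintf("mismatch sweep over %s (%d values, m_IM = %g kg, gamma_IM = %g N s/m)\n",
              x$vary, length(x$values), x$m_im, x$gamma_im))
  for (m in names(x$slopes)) {
    cat(sprintf("  %s: dysmetria ~ early velocity slope %.4f (r = %.3f)\n",
                m, x$slopes[[m]], x$r[[m]]))
  }
  invisible(x)
}
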