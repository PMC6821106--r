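#' @name closed_loop
#' @title Closed-loop matrices for continuous and intermittent control
#'
#' @description
#' These constructors assemble the matrices whose spectra decide the
#' stability of the observer-predictor-feedback loop when the true plant
#' (`Abar`, `Bbar`) differs from the internal model (`A`, `B`) used by the
#' observer, predictor and hold. All gains are time-invariant.
#'
#' * `cc_closedloop_delayfree()`: continuous control, no delay. The
#'   autonomous 8-state system on `x_ov = [x', x_hat']'` with
#'   `A_ov = [[Abar, -Bbar K], [L C, A - B K - L C]]`; stable iff every
#'   eigenvalue has negative real part. When the model is accurate the
#'   spectrum splits into `eig(A - BK)` and `eig(A - LC)` (separation).
#' * `ic_monodromy_delayfree()`: periodic intermittent control with
#'   sampling period `h`, no delay. Returns the 8 x 8 monodromy matrix
#'   `A_p = e^{A_o h} (I - S [0 I])` mapping `x_ov` across one period, where
#'   `S` solves the Sylvester equation `A_o S - S A_F + alpha = 0` with
#'   `alpha = e^{-A_o h} B_o K e^{A_F h} - B_o K`; stable iff the spectral
#'   radius is < 1.
#' * `ic_monodromy_delayed()`: periodic intermittent control with
#'   measurement delay `0 < tau < h`. Returns the 12 x 12 map on
#'   `x_tot = [x_ov[m]', x_p[m-1]']'` assembled from three Sylvester
#'   solutions (the closed forms of the inter-sample integrals over the two
#'   segments `[t_m - tau, t_m)` and `[t_m, t_{m+1} - tau)` of the delayed
#'   time base).
#' * `cc_discrete_delayed()`: continuous control with delay `tau`,
#'   ZOH-discretized at `Delta` (`k_tau = tau/Delta` integer). Returns the
#'   `(8 + 4 k_tau)`-state one-step matrix `A_ex` on
#'   `[x(k-k_tau)', x_hat(k-k_tau)', x_p(k-1)', ..., x_p(k-k_tau)']'`:
#'   delayed plant and observer rows, a predictor row
#'   `x_p(k) = A_d^{k_tau} x_hat(k-k_tau) - sum_j A_d^{j-1} B_d K x_p(k-j)`,
#'   and an identity shift register. Observer gain discretized as
#'   `L_d = L Delta`.
#'
#' The `_oracle_` variants rebuild the same maps by an independent route
#' (block matrix exponentials of the augmented hold dynamics; for the
#' delayed case, method of steps with exact segment solves) and exist to
#' cross-validate the Sylvester constructions.
#'
#' @param Abar,Bbar true plant system and input matrices (4 x 4, 4 x 1).
#' @param A,B,C internal-model system, input and measurement matrices.
#' @param K 1 x 4 feedback gain; `L` 4 x 2 observer gain.
#' @param h sampling period (s), > 0.
#' @param tau measurement delay (s).
#' @param delta discretization step (s); `tau/delta` must be integer.
#' @return the closed-loop matrix described above.
NULL

stack_observer <- function(Abar, A, C, L) {
  n <- nrow(A)
  rbind(cbind(Abar, matrix(0, n, n)),
        cbind(L %*% C, A - L %*% C))
}

#' @rdname closed_loop
#' @export
cc_closedloop_delayfree <- function(Abar, Bbar, A, B, C, K, L) {
  rbind(cbind(Abar, -Bbar %*% K),
        cbind(L %*% C, A - B %*% K - L %*% C))
}

#' @rdname closed_loop
#' @export
ic_monodromy_delayfree <- function(Abar, Bbar, A, B, C, K, L, h) {
  stopifnot(h > 0)
  n <- nrow(A)
  AF <- A - B %*% K
  Ao <- stack_observer(Abar, A, C, L)
  Bo <- rbind(Bbar, B)
  alpha <- expm_mat(-Ao * h) %*% (Bo %*% K) %*% expm_mat(AF * h) - Bo %*% K
  S <- sylvester_solve(Ao, -AF, alpha)
  Z <- cbind(matrix(0, n, n), diag(n))
  expm_mat(Ao * h) %*% (diag(2 * n) - S %*% Z)
}

#' @rdname closed_loop
#' @export
ic_monodromy_oracle_delayfree <- function(Abar, Bbar, A, B, C, K, L, h) {
  stopifnot(h > 0)
  n <- nrow(A)
  AF <- A - B %*% K
  Ao <- stack_observer(Abar, A, C, L)
  Bo <- rbind(Bbar, B)
  # joint flow of (x_ov, x_h) over one period, then the trigger reset
  # x_h(t_m^+) = [0 I] x_ov(t_m)
  M <- rbind(cbind(Ao, -Bo %*% K),
             cbind(matrix(0, n, 2 * n), AF))
  E <- expm_mat(M * h)
  Z <- cbind(matrix(0, n, n), diag(n))
  E[1:(2 * n), 1:(2 * n)] + E[1:(2 * n), (2 * n + 1):(3 * n)] %*% Z
}

#' @rdname closed_loop
#' @export
ic_monodromy_delayed <- function(Abar, Bbar, A, B, C, K, L, h, tau) {
  if (!(tau > 0 && tau < h)) {
    stop("delayed intermittent control requires 0 < tau < h", call. = FALSE)
  }
  n <- nrow(A)
  AF <- A - B %*% K
  Ao <- stack_observer(Abar, A, C, L)
  Bo <- rbind(Bbar, B)
  BK <- B %*% K
  BoK <- Bo %*% K
  S1 <- sylvester_solve(A, -AF, BK - expm_mat(A * tau) %*% BK %*% expm_mat(-AF * tau))
  S2 <- sylvester_solve(Ao, -AF,
                        expm_mat(-Ao * tau) %*% BoK %*% expm_mat(AF * tau) - BoK)
  S3 <- sylvester_solve(Ao, -AF,
                        expm_mat(-Ao * h) %*% BoK %*% expm_mat(AF * h) -
                          expm_mat(-Ao * tau) %*% BoK %*% expm_mat(AF * tau))
  Eh <- expm_mat(Ao * h)
  EFh <- expm_mat(AF * h)
  EFti <- expm_mat(-AF * tau)
  EAt <- expm_mat(A * tau)
  Z <- cbind(matrix(0, n, n), diag(n))
  TL <- Eh %*% (diag(2 * n) - S3 %*% EFti %*% EAt %*% Z)
  TR <- Eh %*% (-S2 %*% EFti + S3 %*% EFti %*% S1) %*% EFh
  BL <- EAt %*% Z
  BR <- -S1 %*% EFh
  rbind(cbind(TL, TR), cbind(BL, BR))
}

#' @rdname closed_loop
#' @export
ic_monodromy_oracle_delayed <- function(Abar, Bbar, A, B, C, K, L, h, tau) {
  if (!(tau > 0 && tau < h)) {
    stop("delayed intermittent control requires 0 < tau < h", call. = FALSE)
  }
  n <- nrow(A)
  AF <- A - B %*% K
  Ao <- stack_observer(Abar, A, C, L)
  Bo <- rbind(Bbar, B)
  Z <- cbind(matrix(0, n, n), diag(n))
  # Method of steps on the delayed time base s = t - tau, solved exactly per
  # segment. Segment 1, s in [t_m - tau, t_m): hold still runs on x_p[m-1];
  # an auxiliary state integrates the predictor so that x_p[m] is available
  # at the segment end. Segment 2, s in [t_m, t_{m+1} - tau): hold reset to
  # x_p[m].
  M1 <- rbind(cbind(Ao, matrix(0, 2 * n, n), -Bo %*% K),
              cbind(matrix(0, n, 2 * n), A, -B %*% K),
              cbind(matrix(0, n, 3 * n), AF))
  E1 <- expm_mat(M1 * tau)
  M2 <- rbind(cbind(Ao, -Bo %*% K),
              cbind(matrix(0, n, 2 * n), AF))
  E2 <- expm_mat(M2 * (h - tau))
  # initial condition as a linear map of [x_ov[m]; x_p[m-1]]
  T0 <- rbind(cbind(diag(2 * n), matrix(0, 2 * n, n)),     # x_ov
              cbind(Z, matrix(0, n, n)),                   # predictor seed
              cbind(matrix(0, n, 2 * n), expm_mat(AF * (h - tau))))  # hold
  Mid <- E1 %*% T0
  xov_tm <- Mid[1:(2 * n), , drop = FALSE]
  xp_m <- Mid[(2 * n + 1):(3 * n), , drop = FALSE]
  fin <- E2 %*% rbind(xov_tm, xp_m)
  rbind(fin[1:(2 * n), , drop = FALSE], xp_m)
}

#' @rdname closed_loop
#' @export
cc_discrete_delayed <- function(Abar, Bbar, A, B, C, K, L, tau, delta = 1e-3) {
  kt <- tau / delta
  if (abs(kt - round(kt)) > 1e-8 || round(kt) < 1) {
    stop("tau/delta must be a positive integer", call. = FALSE)
  }
  kt <- round(kt)
  n <- nrow(A)
  zp <- zoh_discretize(Abar, Bbar, delta)
  zi <- zoh_discretize(A, B, delta)
  Ld <- L * delta
  N <- 2 * n + n * kt
  M <- matrix(0, N, N)
  ix <- function(b) ((b - 1) * n + 1):(b * n)
  M[ix(1), ix(1)] <- zp$Ad
  M[ix(1), ix(2 + kt)] <- -zp$Bd %*% K
  M[ix(2), ix(1)] <- Ld %*% C
  M[ix(2), ix(2)] <- zi$Ad - Ld %*% C
  M[ix(2), ix(2 + kt)] <- -zi$Bd %*% K
  Adp <- diag(n)
  for (j in seq_len(kt)) {
    M[ix(3), ix(2 + j)] <- -Adp %*% zi$Bd %*% K
    Adp <- Adp %*% zi$Ad
  }
  M[ix(3), ix(2)] <- Adp  # A_d^{k_tau}
  if (kt > 1) {
    for (j in 2:kt) M[ix(2 + j), ix(1 + j)] <- diag(n)
  }
  M
}

regime_names <- c("cc_delayfree", "cc_delayed", "ic_delayfree", "ic_delayed")

#' Stability decision statistic for one plant/regime combination
#'
#' Builds the closed-loop matrix of the requested regime for a plant of mass
#' `m_pl` (and damping `gamma_pl`, defaulting to the internal model's) under
#' a given stationary LQG design, and evaluates its decision statistic: the
#' spectral abscissa for the continuous delay-free loop (stable iff < 0), the
#' spectral radius for the three discrete maps (stable iff < 1).
#'
#' @param design an [lqg_design()].
#' @param m_pl true plant mass (kg).
#' @param regime one of `"cc_delayfree"`, `"cc_delayed"`, `"ic_delayfree"`,
#'   `"ic_delayed"`.
#' @param h sampling period (s), intermittent regimes.
#' @param tau measurement delay (s), delayed regimes.
#' @param delta ZOH discretization step (s), `"cc_delayed"` only.
#' @param gamma_pl true plant damping (N s/m); defaults to the internal
#'   model's value.
#' @return object of class `stability_report`: list with `regime`,
#'   `statistic`, `stable`, `limit` and the parameters used.
#' @export
#' @examples
#' d <- lqg_design(2, 8)
#' stability_statistic(d, m_pl = 0.4, regime = "ic_delayfree", h = 0.1)
stability_statistic <- function(design, m_pl,
                                regime = regime_names,
                                h = NULL, tau = NULL, delta = 1e-3,
                                gamma_pl = NULL) {
  stopifnot(inherits(design, "lqg_design"))
  regime <- match.arg(regime)
  if (is.null(gamma_pl)) gamma_pl <- design$model$params$gamma
  pl <- build_plant(plant_params(m_pl, gamma_pl, design$model$params$mu))
  im <- design$model
  M <- switch(regime,
    cc_delayfree = cc_closedloop_delayfree(pl$A, pl$B, im$A, im$B, im$C,
                                           design$K, design$L),
    ic_delayfree = ic_monodromy_delayfree(pl$A, pl$B, im$A, im$B, im$C,
                                          design$K, design$L, h),
    ic_delayed = ic_monodromy_delayed(pl$A, pl$B, im$A, im$B, im$C,
                                      design$K, design$L, h, tau),
    cc_delayed = cc_discrete_delayed(pl$A, pl$B, im$A, im$B, im$C,
                                     design$K, design$L, tau, delta))
  continuous <- regime == "cc_delayfree"
  stat <- if (continuous) spectral_abscissa(M) else spectral_radius(M)
  limit <- if (continuous) 0 else 1
  structure(list(regime = regime, statistic = stat, stable = stat < limit,
                 limit = limit,
                 params = list(m_pl = m_pl, gamma_pl = gamma_pl,
                               m_im = im$params$m, gamma_im = im$params$gamma,
                               v_scale = design$v_scale,
                               h = h, tau = tau, delta = delta)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s: statistic %.6g (%s %g) -> %s\n", x$regime, x$statistic,
              if (x$limit == 0) "limit" else "unit circle", x$limit,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Scan the stability statistic over a grid of plant masses
#'
#' @inheritParams stability_statistic
#' @param m_grid vector of plant masses (kg).
#' @return data.frame with columns `m_pl`, `statistic`, `stable`.
#' @export
stability_scan <- function(design, m_grid, regime = regime_names,
                           h = NULL, tau = NULL, delta = 1e-3,
                           gamma_pl = NULL) {
  regime <- match.arg(regime)
  stats <- vapply(m_grid, function(m) {
    stability_statistic(design, m, regime, h, tau, delta, gamma_pl)$statistic
  }, numeric(1))
  limit <- if (regime == "cc_delayfree") 0 else 1
  data.frame(m_pl = m_grid, statistic = stats, stable = stats < limit)
}

#' Minimum stable plant mass for a control regime
#'
#' Locates the stability threshold of a regime over a bracket of plant
#' masses: the smallest `m_pl` above which the loop is stable for every
#' heavier plant in the bracket. The statistic is evaluated on a coarse
#' grid; the *last* unstable grid point is then refined by bisection to
#' `resolution`. (The statistic can dip below the stability limit in a
#' narrow low-mass window and re-emerge, so the final crossing, not the
#' first, is the reported threshold.)
#'
#' @inheritParams stability_statistic
#' @param bracket mass range scanned (kg), default `c(0.2, 4)`.
#' @param step coarse grid step (kg). Default 0.02, except 0.05 for
#'   `"cc_delayed"` whose matrices are large; the bisection stage sets the
#'   final accuracy either way.
#' @param resolution bisection termination width (kg), default `1e-3`.
#' @return object of class `stability_threshold`: list with `threshold`
#'   (kg, `NA` if no crossing), `sentinel` (`"none"`,
#'   `"stable_everywhere"`, `"unstable_everywhere"`), the regime/parameters,
#'   and the coarse `scan` data.frame.
#' @export
#' @examples
#' \donttest{
#' d <- lqg_design(2, 8)
#' stability_threshold(d, "ic_delayfree", h = 0.05)
#' }
stability_threshold <- function(design, regime = regime_names,
                                h = NULL, tau = NULL, delta = 1e-3,
                                gamma_pl = NULL, bracket = c(0.2, 4),
                                step = NULL, resolution = 1e-3) {
  regime <- match.arg(regime)
  if (is.null(step)) step <- if (regime == "cc_delayed") 0.05 else 0.02
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], step > 0,
            resolution > 0)
  stat1 <- function(m) {
    stability_statistic(design, m, regime, h, tau, delta, gamma_pl)
  }
  grid <- seq(bracket[1], bracket[2], by = step)
  scan <- stability_scan(design, grid, regime, h, tau, delta, gamma_pl)
  out <- list(regime = regime, scan = scan, bracket = bracket,
              params = list(h = h, tau = tau, delta = delta,
                            m_im = design$model$params$m,
                            gamma_im = design$model$params$gamma,
                            v_scale = design$v_scale))
  unstable_idx <- which(!scan$stable)
  if (length(unstable_idx) == 0) {
    out$threshold <- NA_real_
    out$sentinel <- "stable_everywhere"
  } else if (max(unstable_idx) == length(grid)) {
    out$threshold <- NA_real_
    out$sentinel <- "unstable_everywhere"
  } else {
    i <- max(unstable_idx)
    lo <- grid[i]
    hi <- grid[i + 1]
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (stat1(mid)$stable) hi <- mid else lo <- mid
    }
    out$threshold <- hi
    out$sentinel <- "none"
  }
  structure(out, class = "stability_threshold")
}

#' @export
print.stability_threshold <- function(x, ...) {
  lab <- switch(x$sentinel,
                none = sprintf("%.3f kg", x$threshold),
                stable_everywhere = sprintf("< %g kg (stable over the whole bracket)",
                                            x$bracket[1]),
                unstable_everywhere = sprintf("> %g kg (unstable over the whole bracket)",
                                              x$bracket[2]))
  cat(sprintf("%s stability threshold: %s\n", x$regime, lab))
  invisible(x)
}

#' Stability-threshold table across internal models
#'
#' Recomputes the minimum stable plant mass for periodic intermittent
#' control (`h` = 0.2 s) and for ZOH-discretized continuous control at two
#' measurement delays, for a set of internal-model masses and dampings.
#' Plant damping tracks the internal model's in each row.
#'
#' @param m_im,gamma_im vectors of internal-model masses (kg) and dampings
#'   (N s/m); the table has one row per `gamma_im`-major combination.
#' @param h sampling period of the intermittent controller (s).
#' @param taus the two delays evaluated (s).
#' @param delta discretization step for continuous control (s).
#' @param regimes which controller families to tabulate.
#' @param v_scale measurement-noise scale.
#' @param ... further arguments to [stability_threshold()].
#' @return data.frame with one row per internal model and one column per
#'   (regime, tau); thresholds in kg, `-Inf` encoding "stable over the whole
#'   bracket".
#' @export
stability_table <- function(m_im = c(2, 4, 6), gamma_im = c(8, 6), h = 0.2,
                            taus = c(0.1, 0.15), delta = 1e-3,
                            regimes = c("ic", "cc"), v_scale = 1, ...) {
  rows <- expand.grid(m_im = m_im, gamma_im = gamma_im)
  out <- rows
  for (reg in regimes) {
    for (tau in taus) {
      col <- sprintf("%s_tau%g", reg, tau)
      out[[col]] <- vapply(seq_len(nrow(rows)), function(i) {
        d <- lqg_design(rows$m_im[i], rows$gamma_im[i], v_scale = v_scale)
        regime <- if (reg == "ic") "ic_delayed" else "cc_delayed"
        th <- stability_threshold(d, regime, h = h, tau = tau, delta = delta, ...)
        switch(th$sentinel, none = th$threshold,
               stable_everywhere = -Inf, unstable_everywhere = Inf)
      }, numeric(1))
    }
  }
  out
}
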