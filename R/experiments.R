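#' Run a registered experiment
#'
#' Reproduces one of the package's standard analyses end to end and writes
#' its outputs (CSV tables, JSON sidecars and a manifest) to `out_dir`.
#' Experiments are deterministic given their parameters and seed; re-running
#' one produces byte-identical CSVs. No result values are computed in this
#' layer — it only wires module functions together and serializes.
#'
#' Registered ids:
#' * `"stability_curves"` — spectral-radius / spectral-abscissa curves over a
#'   plant-mass grid for intermittent control at several sampling periods and
#'   for continuous control, delay-free (`v_scale` selects V0 vs V0/10).
#' * `"stability_curves_delayed"` — the delayed counterparts: intermittent
#'   control at `h` = 0.2 s over delays, and ZOH-discretized continuous
#'   control.
#' * `"threshold_table"` — the minimum-stable-mass table across internal
#'   models (intermittent and continuous control at two delays).
#' * `"reach_traces"` — stationary-gain reaching simulations classifying
#'   stability for chosen `(mode, h, tau, v_scale)` combinations.
#' * `"mismatch_traces"` — time-varying-gain reaches with inaccurately
#'   modelled mass or damping (position/velocity traces).
#' * `"dysmetria_sweep"` — [mismatch_sweep()] plus regression sidecar.
#'
#' @param id experiment id (see above).
#' @param overrides named list overriding the experiment's default
#'   parameters (validated against the defaults; unknown names error).
#' @param out_dir output directory, created if needed.
#' @param seed integer seed recorded in the manifest and used for any noisy
#'   simulation.
#' @param config optional path to a YAML file of overrides, merged beneath
#'   `overrides`.
#' @return (invisibly) the manifest list; files are written to `out_dir`.
#' @export
run_experiment <- function(id, overrides = list(), out_dir = "results",
                           seed = 1L, config = NULL) {
  reg <- experiment_registry()
  if (!id %in% names(reg)) {
    stop("unknown experiment id '", id, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  spec <- reg[[id]]
  params <- spec$defaults
  if (!is.null(config)) {
    cfgl <- yaml::read_yaml(config)
    overrides <- utils::modifyList(cfgl, overrides)
  }
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    stop("unknown override(s) for '", id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(params, overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  files <- spec$run(params, out_dir, as.integer(seed))
  manifest <- list(id = id, parameters = params, seed = as.integer(seed),
                   files = files,
                   package_version = as.character(utils::packageVersion("icreach")),
                   elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(id, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

experiment_registry <- function() {
  list(
    stability_curves = list(
      defaults = list(v_scale = 1, m_im = 2, gamma_im = 8,
                      hs = c(0.05, 0.1, 0.2), m_grid_step = 0.05,
                      bracket = c(0.2, 4)),
      run = function(p, out_dir, seed) {
        d <- lqg_design(p$m_im, p$gamma_im, v_scale = p$v_scale)
        grid <- seq(p$bracket[1], p$bracket[2], by = p$m_grid_step)
        parts <- lapply(p$hs, function(h) {
          sc <- stability_scan(d, grid, "ic_delayfree", h = h)
          cbind(data.frame(regime = sprintf("ic_h%g", h)), sc)
        })
        sc_cc <- cbind(data.frame(regime = "cc"),
                       stability_scan(d, grid, "cc_delayfree"))
        write_result_csv(do.call(rbind, c(parts, list(sc_cc))),
                         file.path(out_dir, "stability_curves.csv"))
      }),
    stability_curves_delayed = list(
      defaults = list(v_scale = 1, m_im = 2, gamma_im = 8, h = 0.2,
                      taus_ic = c(0.1, 0.15), taus_cc = c(0.001, 0.1, 0.15),
                      delta = 1e-3, m_grid_step = 0.05, bracket = c(0.2, 4)),
      run = function(p, out_dir, seed) {
        d <- lqg_design(p$m_im, p$gamma_im, v_scale = p$v_scale)
        grid <- seq(p$bracket[1], p$bracket[2], by = p$m_grid_step)
        parts <- c(
          lapply(p$taus_ic, function(tau) {
            cbind(data.frame(regime = sprintf("ic_tau%g", tau)),
                  stability_scan(d, grid, "ic_delayed", h = p$h, tau = tau))
          }),
          lapply(p$taus_cc, function(tau) {
            cbind(data.frame(regime = sprintf("cc_tau%g", tau)),
                  stability_scan(d, grid, "cc_delayed", tau = tau,
                                 delta = p$delta))
          }))
        write_result_csv(do.call(rbind, parts),
                         file.path(out_dir, "stability_curves_delayed.csv"))
      }),
    threshold_table = list(
      defaults = list(m_im = c(2, 4, 6), gamma_im = c(8, 6), h = 0.2,
                      taus = c(0.1, 0.15), delta = 1e-3,
                      regimes = c("ic", "cc"), v_scale = 1),
      run = function(p, out_dir, seed) {
        tab <- stability_table(p$m_im, p$gamma_im, p$h, p$taus, p$delta,
                               p$regimes, p$v_scale)
        write_result_csv(tab, file.path(out_dir, "threshold_table.csv"))
      }),
    reach_traces = list(
      defaults = list(m_im = 2, gamma_im = 8, m_pl = 0.4, gamma_pl = 8,
                      v_scale = 1, noise = TRUE, duration = 6,
                      runs = list(list(mode = "ic", h = 0.1, tau = 0),
                                  list(mode = "ic", h = 0.2, tau = 0),
                                  list(mode = "cc", h = 0.2, tau = 0))),
      run = function(p, out_dir, seed) {
        d <- lqg_design(p$m_im, p$gamma_im, v_scale = p$v_scale)
        plant <- plant_params(p$m_pl, p$gamma_pl)
        files <- character(0)
        summary <- list()
        for (r in p$runs) {
          cfg <- sim_config(duration = p$duration, tau = r$tau, h = r$h,
                            noise = p$noise, seed = seed,
                            gain_mode = "stationary")
          tr <- if (r$mode == "cc") simulate_cc(d, plant, cfg)
                else simulate_ic(d, plant, cfg)
          tag <- sprintf("%s_h%g_tau%g", r$mode, r$h, r$tau)
          files <- c(files, write_result_csv(
            as.data.frame(tr), file.path(out_dir, paste0("trace_", tag, ".csv"))))
          summary[[tag]] <- list(diverged = reach_diverged(tr))
        }
        jsonlite::write_json(summary,
                             file.path(out_dir, "reach_traces_verdicts.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        c(files, file.path(out_dir, "reach_traces_verdicts.json"))
      }),
    mismatch_traces = list(
      defaults = list(vary = "mass", m_im = 2, gamma_im = 8,
                      offsets = c(-0.5, 0, 0.5), tau = 0.15, h = 0.2,
                      duration = 1.5),
      run = function(p, out_dir, seed) {
        d <- lqg_design(p$m_im, p$gamma_im)
        cfg <- sim_config(duration = p$duration, tau = p$tau, h = p$h)
        parts <- list()
        for (off in p$offsets) {
          plant <- if (p$vary == "mass") plant_params(p$m_im + off, p$gamma_im)
                   else plant_params(p$m_im, p$gamma_im + 2 * off)
          for (mode in c("cc", "ic")) {
            tr <- if (mode == "cc") simulate_cc(d, plant, cfg)
                  else simulate_ic(d, plant, cfg)
            parts[[length(parts) + 1]] <-
              cbind(data.frame(offset = off, mode = mode), as.data.frame(tr))
          }
        }
        write_result_csv(do.call(rbind, parts),
                         file.path(out_dir,
                                   sprintf("mismatch_traces_%s.csv", p$vary)))
      }),
    dysmetria_sweep = list(
      defaults = list(vary = "mass", m_im = 2, gamma_im = 8, n = 9,
                      cost = "nominal", duration = 1.5, tau = 0.15, h = 0.2),
      run = function(p, out_dir, seed) {
        Q <- if (identical(p$cost, "modified")) diag(c(1, 0.1^2, 0.02^2, 0))
             else diag(c(1, 0.2^2, 0.02^2, 0))
        cfg <- sim_config(duration = p$duration, tau = p$tau, h = p$h)
        sw <- mismatch_sweep(p$vary, p$m_im, p$gamma_im, n = p$n,
                             Q_inf = Q, cfg = cfg)
        f1 <- write_result_csv(sw$results,
                               file.path(out_dir,
                                         sprintf("dysmetria_sweep_%s.csv", p$vary)))
        side <- lapply(names(sw$fits), function(m) {
          f <- sw$fits[[m]]
          list(mode = m, slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               r = unname(sw$r[[m]]), n = stats::nobs(f))
        })
        f2 <- file.path(out_dir, sprintf("dysmetria_regression_%s.json", p$vary))
        jsonlite::write_json(side, f2, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
        c(f1, f2)
      })
  )
}
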