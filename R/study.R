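#' Default study configuration
#'
#' Returns the full configuration of the three-arm study
#' (healthy / infarcted / device-treated) with every tunable parameter
#' at its documented default.  The structure mirrors the module
#' constructors; any subset can be overridden via YAML
#' ([validate_config()]) or by modifying the returned list.
#'
#' @return An object of class `study_config` (a named nested list).
#' @export
study_config <- function() {
  structure(list(
    materials = list(k = 1000, a = 0.33, b = 7.08, a_ff = 0.25,
                     b_ff = 5.34, a_ss = 0, b_ss = 0, a_fs = 0, b_fs = 0),
    active = list(t_act = 0, t_dur = 0.4, length_dep = 6),
    ventricle = list(v_wall_ml = 150, v_cav_ref_ml = 40, aspect = 1),
    circulation = list(p_ven = 1.1, r_mv = 0.008, r_av = 0.006,
                       c_art = 12, r_per = 0.14, p_art_init = 11,
                       k_orifice = 0.82, period = 1.0, dt = 0.001),
    valve = list(n_strips = 12, d_ref_mm = 30, v_ref_ml = 120,
                 anterior_len_mm = 24, posterior_len_mm = 14,
                 n_seg_anterior = 6, n_seg_posterior = 5,
                 thickness_mm = 1, pap_depth_mm = 20, pap_x_frac = 0.6,
                 slack_factor = 0.94,
                 chordae_area_basal_mm2 = 0.6,
                 chordae_area_marginal_mm2 = 0.35),
    device = list(undersize_factor = 0.85, ring_plane_offset = 0,
                  subvalvular_depth = 6, subvalvular_reach = 4.5,
                  subvalvular_radius = 3.5, enabled_subvalvular = TRUE),
    contact = list(penalty_stiffness = 400, gap_tol = 0.05,
                   max_newton_iters = 200, residual_tol = 1e-8),
    infarct = list(ef_target = 0.45, sizing_tol = 0.0025,
                   phi = NULL, pap_disp_scale_mm = NULL),
    calibration = list(ef_target = 0.55, shortening_target_mm = 12.1,
                       chordae_target = 0.78, fit_noise_sd_frac = 0.02),
    study = list(n_times = 20, seed = 1)
  ), class = "study_config")
}

# bounds and types checked by validate_config: list of
# section -> field -> c(lo, hi) (NA = unbounded)
.config_bounds <- list(
  materials = list(k = c(0, Inf), a = c(0, Inf), b = c(0, Inf),
                   a_ff = c(0, Inf), b_ff = c(0, Inf), a_ss = c(0, Inf),
                   b_ss = c(0, Inf), a_fs = c(0, Inf), b_fs = c(0, Inf)),
  active = list(t_act = c(0, Inf), t_dur = c(1e-6, Inf),
                length_dep = c(0, Inf)),
  ventricle = list(v_wall_ml = c(1e-6, Inf), v_cav_ref_ml = c(1e-6, Inf),
                   aspect = c(1e-6, Inf)),
  circulation = list(p_ven = c(0, Inf), r_mv = c(1e-9, Inf),
                     r_av = c(1e-9, Inf), c_art = c(1e-9, Inf),
                     r_per = c(1e-9, Inf), p_art_init = c(0, Inf),
                     k_orifice = c(0, Inf), period = c(1e-3, Inf),
                     dt = c(1e-6, Inf)),
  valve = list(n_strips = c(6, 120), d_ref_mm = c(1, Inf),
               v_ref_ml = c(1, Inf), anterior_len_mm = c(1e-6, Inf),
               posterior_len_mm = c(1e-6, Inf),
               n_seg_anterior = c(2, 60), n_seg_posterior = c(2, 60),
               thickness_mm = c(1e-3, Inf), pap_depth_mm = c(0, Inf),
               pap_x_frac = c(0, 1), slack_factor = c(0.5, 1.1),
               chordae_area_basal_mm2 = c(1e-6, Inf),
               chordae_area_marginal_mm2 = c(1e-6, Inf)),
  device = list(undersize_factor = c(0.5, 1),
                ring_plane_offset = c(-Inf, Inf),
                subvalvular_depth = c(0, Inf),
                subvalvular_reach = c(0, Inf),
                subvalvular_radius = c(1e-6, Inf),
                enabled_subvalvular = NULL),
  contact = list(penalty_stiffness = c(1e-9, Inf), gap_tol = c(1e-6, Inf),
                 max_newton_iters = c(1, 1e6), residual_tol = c(0, 1)),
  infarct = list(ef_target = c(0, 1), sizing_tol = c(1e-6, 1),
                 phi = c(0, 0.6), pap_disp_scale_mm = c(0, Inf)),
  calibration = list(ef_target = c(0, 1),
                     shortening_target_mm = c(0, Inf),
                     chordae_target = c(0, Inf),
                     fit_noise_sd_frac = c(0, 1)),
  study = list(n_times = c(2, 1000), seed = c(-2^31, 2^31))
)

#' Load and validate a study configuration
#'
#' Reads a YAML file (or takes a list) of overrides to
#' [study_config()], rejecting unknown sections or keys and values
#' outside their physical bounds.  Every violation is collected and
#' reported together, not just the first.
#'
#' @param path YAML file path, or a named list of overrides.
#' @return A validated `study_config` with overrides applied.
#' @export
validate_config <- function(path) {
  ov <- if (is.character(path)) {
    if (!file.exists(path)) stop("validate_config: file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop("validate_config: path must be a file path or a list")
  if (is.null(ov)) ov <- list()
  cfg <- study_config()
  errs <- character()
  for (sec in names(ov)) {
    if (!sec %in% names(cfg)) {
      errs <- c(errs, paste0("unknown section '", sec, "'"))
      next
    }
    for (key in names(ov[[sec]])) {
      if (!key %in% names(.config_bounds[[sec]])) {
        errs <- c(errs, paste0("unknown key '", sec, ".", key, "'"))
        next
      }
      val <- ov[[sec]][[key]]
      bd <- .config_bounds[[sec]][[key]]
      if (is.null(bd)) {                       # logical field
        if (!is.logical(val) || length(val) != 1L || is.na(val)) {
          errs <- c(errs, paste0("'", sec, ".", key, "' must be TRUE/FALSE"))
          next
        }
      } else {
        if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
          errs <- c(errs, paste0("'", sec, ".", key,
                                 "' must be a single finite number"))
          next
        }
        if (val < bd[1] || val > bd[2]) {
          errs <- c(errs, paste0("'", sec, ".", key, "' = ", val,
                                 " outside [", bd[1], ", ", bd[2], "]"))
          next
        }
      }
      cfg[[sec]][[key]] <- val
    }
  }
  if (length(errs))
    stop("validate_config: ", length(errs), " violation(s):\n  - ",
         paste(errs, collapse = "\n  - "))
  cfg
}

# assemble model objects from a validated config
.config_model <- function(cfg) {
  list(
    geom = ventricle_geometry(cfg$ventricle$v_wall_ml,
                              cfg$ventricle$v_cav_ref_ml,
                              cfg$ventricle$aspect),
    params = do.call(ho_params, cfg$materials),
    act = active_law(T_max = 110, t_act = cfg$active$t_act,
                     t_dur = cfg$active$t_dur,
                     length_dep = cfg$active$length_dep),
    circ = do.call(circulation_params, cfg$circulation)
  )
}

.config_valve <- function(cfg, laws) {
  v <- cfg$valve
  valve_geometry(
    n_strips = v$n_strips, d_ref_mm = v$d_ref_mm, v_ref_ml = v$v_ref_ml,
    anterior_len_mm = v$anterior_len_mm,
    posterior_len_mm = v$posterior_len_mm,
    n_seg_anterior = v$n_seg_anterior, n_seg_posterior = v$n_seg_posterior,
    thickness_mm = v$thickness_mm, pap_depth_mm = v$pap_depth_mm,
    pap_x_frac = v$pap_x_frac, slack_factor = v$slack_factor,
    chordae_area_mm2 = c(basal = v$chordae_area_basal_mm2,
                         marginal = v$chordae_area_marginal_mm2),
    laws = laws)
}

#' Run the full three-arm study
#'
#' Executes, in order: material-law fitting on seeded synthetic
#' leaflet/chordae fixtures; healthy-baseline calibration (peak active
#' tension to the target ejection fraction, shape factor to the target
#' long-axis shortening); the healthy arm; infarct sizing by bisection
#' to the post-infarct EF target; calibration of the papillary
#' displacement scale to the post-infarct normalized chordae-force
#' peak; the infarcted arm (valve-leak coupled); device attachment and
#' the treated arm with all parameters frozen.  The pipeline contains
#' no randomness beyond the seeded fixture generator, so reruns with
#' the same configuration are identical.
#'
#' @param config a `study_config` (from [study_config()] or
#'   [validate_config()]).
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, per-arm `cycle_<arm>.csv`,
#'   `valve_solutions_<arm>.csv`, `chordae_trace_<arm>.csv`, fitted-law
#'   and PV-loop / trace PNG figures.
#' @return An object of class `study_report` (list): `arms` (per-arm
#'   scalar outcomes), `laws` (fitted tissue laws), `infarct` (sized
#'   region with calibrated displacement scale), `model` (calibrated
#'   configuration), and the per-arm cycle/valve objects.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cal <- config$calibration

  # 1. material fitting on synthetic fixtures (the only seeded stage)
  laws <- fit_tissue_laws(noise_sd = cal$fit_noise_sd_frac,
                          seed = config$study$seed)

  # 2. healthy calibration
  model <- .config_model(config)
  model <- calibrate_healthy(model, ef_target = cal$ef_target,
                             shortening_target_mm = cal$shortening_target_mm)
  geom <- .config_valve(config, laws)
  contact <- do.call(contact_params, config$contact)
  n_times <- config$study$n_times

  # 3. healthy arm
  healthy <- run_coupled_arm(model, geom, contact = contact,
                             n_times = n_times)
  healthy_peak <- max(healthy$valve$avg_pm_force_N)

  # 4. infarct sizing
  inf0 <- if (!is.null(config$infarct$phi))
    infarct_region(config$infarct$phi)
  else size_infarct(model, config$infarct$ef_target,
                    tol = config$infarct$sizing_tol)

  # 5. papillary displacement calibration (unless pinned by config)
  if (!is.null(config$infarct$pap_disp_scale_mm)) {
    inf <- infarct_region(inf0$phi, config$infarct$pap_disp_scale_mm)
    infarcted <- run_coupled_arm(model, geom, infarct = inf,
                                 contact = contact, n_times = n_times,
                                 warm = healthy$valve)
  } else {
    inf <- calibrate_pap_disp_scale(model, geom, inf0, healthy_peak,
                                    target = cal$chordae_target,
                                    contact = contact, n_times = n_times,
                                    warm0 = healthy$valve)
    infarcted <- attr(inf, "arm")
    attr(inf, "arm") <- NULL
  }

  # 6. treated arm: same infarct, device attached, nothing re-tuned.
  # The device changes the annulus frame, so the tethered treated state
  # is reached by continuation: the device is first solved on the
  # untethered heart and the papillary displacement is then ramped up
  # to its calibrated value in small steps before the coupled run
  device <- do.call(device_geometry, config$device)
  vs_seed <- NULL
  s_cal <- inf$pap_disp_scale_mm
  for (s_i in seq(0, s_cal, length.out = max(2, ceiling(s_cal / 5) + 1))) {
    vs_seed <- solve_valve(geom, infarcted$cycle,
                           infarct = infarct_region(inf$phi, s_i),
                           device = device, contact = contact,
                           n_times = n_times,
                           p_ven_kpa = config$circulation$p_ven,
                           warm = vs_seed)
  }
  treated <- run_coupled_arm(model, geom, infarct = inf, device = device,
                             contact = contact, n_times = n_times,
                             warm = vs_seed)

  arm_summary <- function(arm, nm) {
    cy <- arm$cycle
    data.frame(
      arm = nm, EDV_ml = cy$EDV, ESV_ml = cy$ESV, EF_pct = 100 * cy$EF,
      shortening_mm = cy$shortening,
      regurgitant_volume_ml = cy$regurgitant_volume,
      peak_P_lv_kPa = max(cy$P_lv),
      max_A_gap_mm2 = max(arm$valve$A_gap),
      peak_chordae_force_N = max(arm$valve$avg_pm_force_N),
      peak_chordae_norm = max(arm$valve$avg_pm_force_N) / healthy_peak)
  }
  arms <- rbind(arm_summary(healthy, "healthy"),
                arm_summary(infarcted, "infarcted"),
                arm_summary(treated, "treated"))

  report <- structure(list(
    arms = arms, laws = laws, infarct = inf, model = model,
    healthy = healthy, infarcted = infarcted, treated = treated,
    healthy_peak_N = healthy_peak, config = config
  ), class = "study_report")
  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  df <- x$arms
  df[, -1] <- signif(df[, -1], 4)
  print(df, row.names = FALSE)
  cat("infarct: phi =", signif(x$infarct$phi, 4),
      " pap_disp_scale =", signif(x$infarct$pap_disp_scale_mm, 4), "mm\n")
  invisible(x)
}

#' Write all study artifacts to a directory
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arms <- c("healthy", "infarcted", "treated")
  for (nm in arms) {
    arm <- report[[nm]]
    cy <- arm$cycle
    utils::write.csv(
      data.frame(t = cy$t, V_ml = cy$V_lv, P_lv_kPa = cy$P_lv,
                 P_art_kPa = cy$P_art, L_mm = cy$L, Q_reg_ml_s = cy$Q_reg),
      file.path(out_dir, paste0("cycle_", nm, ".csv")), row.names = FALSE)
    utils::write.csv(arm$valve$strips,
                     file.path(out_dir, paste0("valve_solutions_", nm,
                                               ".csv")), row.names = FALSE)
    utils::write.csv(
      chordae_force_trace(arm$valve, report$healthy_peak_N),
      file.path(out_dir, paste0("chordae_trace_", nm, ".csv")),
      row.names = FALSE)
  }
  rep_list <- list(
    arms = report$arms,
    infarct = list(phi = report$infarct$phi,
                   pap_disp_scale_mm = report$infarct$pap_disp_scale_mm),
    calibrated = list(T_max_kPa = report$model$act$T_max,
                      aspect = report$model$geom$aspect),
    fitted_laws = lapply(report$laws, function(l)
      list(A_kPa = l$A, B = l$B)),
    healthy_peak_chordae_force_N = report$healthy_peak_N)
  jsonlite::write_json(rep_list, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  plot_study(report, out_dir)
  invisible(out_dir)
}

#' Study figures
#'
#' Writes PV-loop overlay, long-axis shortening, and normalized
#' chordae-force trace figures as PNG.
#'
#' @param report a [run_study()] result.
#' @param out_dir directory for the PNG files.
#' @return `out_dir`, invisibly.
#' @export
plot_study <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c(healthy = "black", infarcted = "blue", treated = "red")
  grDevices::png(file.path(out_dir, "pv_loops.png"), width = 900,
                 height = 750, res = 150)
  graphics::plot(NA, xlim = range(sapply(c("healthy", "infarcted",
                                           "treated"), function(nm)
    range(report[[nm]]$cycle$V_lv))),
    ylim = c(0, max(report$healthy$cycle$P_lv) * 1.05),
    xlab = "LV volume (mL)", ylab = "LV pressure (kPa)",
    main = "LV pressure-volume loops")
  for (nm in names(cols)) {
    cy <- report[[nm]]$cycle
    graphics::lines(cy$V_lv, cy$P_lv, col = cols[nm], lwd = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "long_axis_shortening.png"),
                 width = 900, height = 750, res = 150)
  cy <- report$healthy$cycle
  graphics::plot(cy$t, max(cy$L) - cy$L, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "long-axis shortening (mm)",
                 main = "Healthy LV long-axis shortening")
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "chordae_traces.png"), width = 900,
                 height = 750, res = 150)
  graphics::plot(NA, xlim = range(report$healthy$valve$t), ylim = c(0, 1.4),
                 xlab = "time (s)",
                 ylab = "normalized avg posterior chordae force",
                 main = "Chordae force (normalized to healthy peak)")
  for (nm in names(cols)) {
    tr <- chordae_force_trace(report[[nm]]$valve, report$healthy_peak_N)
    graphics::lines(tr$t, tr$force_norm, col = cols[nm], lwd = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  grDevices::dev.off()
  invisible(out_dir)
}
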