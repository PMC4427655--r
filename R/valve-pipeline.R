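#' Solve the mitral valve over systole
#'
#' Samples the systolic (ejection) phase of a converged cardiac cycle
#' at `n_times` instants and solves every strip's quasi-static
#' equilibrium at each.  The annulus diameter follows
#' `D(t) = d_ref * (V(t)/v_ref)^(1/3)` (frozen by the rigid ring when a
#' device is attached); an infarct displaces the posteromedial
#' papillary tips apically and laterally (2:1) by
#' `phi * pap_disp_scale_mm`; the transvalvular pressure is
#' `P_lv(t) - p_ven`.  The sweep runs chronologically with warm
#' starts, so all samples follow one equilibrium branch; a previous
#' `valve_series` can seed the sweep (`warm`) so parameter studies are
#' continuations too.
#'
#' @param geom a [valve_geometry()].
#' @param cycle a converged [run_cycle()] result.
#' @param infarct optional [infarct_region()].
#' @param device optional [device_geometry()]; attached via
#'   [attach_device()] before solving.
#' @param contact a [contact_params()].
#' @param n_times number of systolic sample instants.
#' @param p_ven_kpa venous (atrial) pressure used for the
#'   transvalvular load (kPa).
#' @param warm optional previous `valve_series` from a comparable
#'   configuration; its equilibrium states seed the solves so that a
#'   parameter sweep follows one equilibrium branch continuously.
#' @return An object of class `valve_series`: `t` (sampled times),
#'   `A_gap` (regurgitant gap area, mm^2), `avg_pm_force_N` (average
#'   posterior-papillary chordae tension), `strips` (long data.frame:
#'   t, strip, sector, coaptation_mm, gap_mm, F_basal_N, F_marginal_N,
#'   contact), and `per_time` (list of per-class solutions).
#' @export
solve_valve <- function(geom, cycle, infarct = NULL, device = NULL,
                        contact = contact_params(), n_times = 20,
                        p_ven_kpa = 1.1, warm = NULL) {
  stopifnot(inherits(geom, "valve_geometry"),
            inherits(cycle, "cycle_result"))
  if (!cycle$converged)
    stop("solve_valve: cycle must be converged")
  if (!is.null(device)) geom <- attach_device(geom, device)

  # ejection window; fall back to the upper half of the pressure pulse
  idx <- which(cycle$P_lv > cycle$P_art)
  if (length(idx) < 2) idx <- which(cycle$P_lv > 0.5 * max(cycle$P_lv))
  if (length(idx) < 2) stop("solve_valve: no systolic phase in the cycle")
  ts <- seq(cycle$t[min(idx)], cycle$t[max(idx)], length.out = n_times)
  p_lv <- stats::approx(cycle$t, cycle$P_lv, ts, rule = 2)$y
  v_lv <- stats::approx(cycle$t, cycle$V_lv, ts, rule = 2)$y
  d_t <- geom$d_ref_mm * (v_lv / geom$v_ref_ml)^(1 / 3)

  phi <- if (is.null(infarct)) 0 else infarct$phi
  mag <- if (is.null(infarct)) 0 else infarct$phi * infarct$pap_disp_scale_mm
  disp <- c(mag / sqrt(5), -2 * mag / sqrt(5))     # lateral : apical = 1 : 2

  pm <- seq_len(geom$n_strips) %in% geom$pm_strips
  warm_series <- if (!is.null(warm)) warm$per_time else NULL

  A_gap <- numeric(n_times)
  avg_f <- numeric(n_times)
  strips_list <- vector("list", n_times)
  per_time <- vector("list", n_times)
  # chronological sweep with warm starts: each instant continues the
  # equilibrium branch of the previous one (the quasi-static image of
  # the loading path through systole)
  order_idx <- seq_len(n_times)
  warm_from <- c(0L, seq_len(n_times - 1))
  u_store <- vector("list", n_times)
  for (i in order_idx) {
    dp <- max(0, p_lv[i] - p_ven_kpa)
    w_strip <- pi * (if (is.null(geom$device)) d_t[i] else
      geom$device$undersize_factor * geom$d_ref_mm) / geom$n_strips
    sols <- vector("list", geom$n_strips)
    u_now <- vector("list", geom$n_strips)
    for (k in seq_len(geom$n_strips)) {
      pap <- if (pm[k] && mag > 0) geom$pap_tips[k, ] + disp else NULL
      # the anterior leaflet is supported by chordae from both
      # papillary muscles; the anterolateral one is remote from the
      # infarct, so the anterior tether anchor stays at its healthy
      # position
      pap_a <- if (pm[k] && mag > 0) geom$pap_tips[k, ] else NULL
      u0 <- if (!is.null(warm_series) && length(warm_series) >= i &&
                length(warm_series[[i]]) >= k)
        warm_series[[i]][[k]]$u
      else if (warm_from[i] > 0L) u_store[[warm_from[i]]][[k]]
      else NULL
      s <- solve_strip(geom, k, dp_kpa = dp, d_mm = d_t[i],
                       contact = contact, pap_tip = pap,
                       pap_tip_ant = pap_a, u0 = u0)
      u_now[[k]] <- s$u
      sols[[k]] <- s
    }
    u_store[[i]] <- u_now
    gap_i <- vapply(sols, function(s) s$gap_mm, 0)
    A_gap[i] <- sum(gap_i * w_strip)
    pm_f <- vapply(sols[pm], function(s)
      mean(c(s$forces_N[["p_basal"]], s$forces_N[["p_marginal"]])), 0)
    avg_f[i] <- mean(pm_f)
    strips_list[[i]] <- data.frame(
      t = ts[i], strip = seq_len(geom$n_strips), sector = geom$sector,
      coaptation_mm = vapply(sols, function(s) s$coaptation_mm, 0),
      gap_mm = gap_i,
      F_basal_N = vapply(sols, function(s) s$forces_N[["p_basal"]], 0),
      F_marginal_N = vapply(sols, function(s) s$forces_N[["p_marginal"]], 0),
      contact = vapply(sols, function(s) s$contact_active, TRUE))
    per_time[[i]] <- sols
  }
  strips_df <- do.call(rbind, strips_list)
  structure(list(t = ts, A_gap = A_gap, avg_pm_force_N = avg_f,
                 strips = strips_df, per_time = per_time,
                 dp_kpa = pmax(0, p_lv - p_ven_kpa), d_mm = d_t),
            class = "valve_series")
}

#' @export
print.valve_series <- function(x, ...) {
  cat("<valve_series>", length(x$t), "systolic samples\n",
      " peak avg posterior chordae force:",
      signif(max(x$avg_pm_force_N), 4), "N\n",
      " max regurgitant gap area:", signif(max(x$A_gap), 4), "mm^2\n")
  invisible(x)
}

#' Normalized average chordae-force time course
#'
#' Averages the posterior-papillary chordae tensions at each sampled
#' time and normalizes by a reference peak (the healthy heart's peak
#' average force); the healthy trace normalized by its own peak
#' has maximum exactly 1.
#'
#' @param series a [solve_valve()] result.
#' @param normalize_by reference peak force (N); defaults to the
#'   trace's own peak.
#' @return data.frame with `t`, `force_N`, `force_norm`.
#' @export
chordae_force_trace <- function(series, normalize_by = NULL) {
  stopifnot(inherits(series, "valve_series"))
  f <- series$avg_pm_force_N
  if (length(f) == 0) stop("chordae_force_trace: empty series")
  if (is.null(normalize_by)) normalize_by <- max(f)
  if (normalize_by <= 0)
    stop("chordae_force_trace: reference peak must be > 0")
  data.frame(t = series$t, force_N = f, force_norm = f / normalize_by)
}

#' Run one arm of the study with valve-leak coupling
#'
#' Runs the cardiac cycle, solves the valve over systole, feeds the
#' regurgitant gap area back into the circulation as a leak orifice,
#' and iterates to a fixed point (change in gap area below
#' `a_gap_tol` between passes, at most `max_passes` passes).
#'
#' @param model ventricle-circulation configuration (see
#'   [run_cycle()]).
#' @param geom a [valve_geometry()].
#' @param infarct optional [infarct_region()].
#' @param device optional [device_geometry()].
#' @param contact a [contact_params()].
#' @param n_times systolic samples per pass.
#' @param a_gap_tol fixed-point tolerance on the gap area (mm^2).
#' @param max_passes maximum coupling passes.
#' @param warm optional `valve_series` seed (see [solve_valve()]).
#' @return List with `cycle` (final [run_cycle()] result), `valve`
#'   (final [solve_valve()] series), `passes`, `coupled_converged`.
#' @export
run_coupled_arm <- function(model, geom, infarct = NULL, device = NULL,
                            contact = contact_params(), n_times = 20,
                            a_gap_tol = 1, max_passes = 8, warm = NULL) {
  cycle <- run_cycle(model, infarct = infarct)
  a_prev <- rep(0, n_times)
  a_fb <- rep(0, n_times)
  vs <- NULL
  converged <- FALSE
  passes <- 0L
  for (k in seq_len(max_passes)) {
    passes <- k
    vs <- solve_valve(geom, cycle, infarct = infarct, device = device,
                      contact = contact, n_times = n_times,
                      p_ven_kpa = model$circ$p_ven, warm = warm)
    warm <- vs
    if (max(abs(vs$A_gap - a_prev)) < a_gap_tol) { converged <- TRUE; break }
    # under-relax the fed-back gap area for fixed-point stability
    a_fb <- if (k == 1) vs$A_gap else 0.5 * vs$A_gap + 0.5 * a_fb
    a_prev <- vs$A_gap
    gap_fun <- stats::approxfun(vs$t, a_fb, rule = 2)
    cycle <- run_cycle(model, infarct = infarct, a_gap = gap_fun)
  }
  list(cycle = cycle, valve = vs, passes = passes,
       coupled_converged = converged)
}

#' Calibrate the papillary displacement scale
#'
#' One-dimensional root finding on `pap_disp_scale_mm`: the infarcted
#' arm (with valve-leak coupling) is evaluated at candidate scales and
#' the scale is chosen so the peak average posterior chordae force,
#' normalized by the healthy peak, matches `target` (default 0.78).
#' A coarse grid locates a bracket, bisection refines it.
#'
#' @param model calibrated healthy model configuration.
#' @param geom a [valve_geometry()].
#' @param infarct sized [infarct_region()] (its `phi` is kept).
#' @param healthy_peak_N healthy peak average posterior chordae force.
#' @param target target normalized peak (fraction of healthy).
#' @param s_max largest scale considered (mm per unit phi).
#' @param tol acceptable |achieved - target|.
#' @param warm0 optional `valve_series` (typically the healthy arm's)
#'   seeding the first evaluation, so the scan is a continuation from
#'   the healthy state.
#' @param ... passed to [run_coupled_arm()].
#' @return The calibrated [infarct_region()] with attributes
#'   `achieved_ratio` and `arm` (the infarcted-arm results at the
#'   calibrated scale).
#' @export
calibrate_pap_disp_scale <- function(model, geom, infarct,
                                     healthy_peak_N, target = 0.78,
                                     s_max = 80, tol = 0.005,
                                     warm0 = NULL, ...) {
  warm <- warm0
  ratio_at <- function(s) {
    inf <- infarct_region(infarct$phi, s)
    arm <- run_coupled_arm(model, geom, infarct = inf, warm = warm, ...)
    warm <<- arm$valve
    list(r = max(arm$valve$avg_pm_force_N) / healthy_peak_N, arm = arm,
         inf = inf)
  }
  grid <- seq(0, s_max, length.out = 9)
  vals <- vector("list", length(grid))
  bracket <- NULL
  for (i in seq_along(grid)) {
    vals[[i]] <- ratio_at(grid[i])
    if (i > 1) {
      r1 <- vals[[i - 1]]$r; r2 <- vals[[i]]$r
      if ((r1 - target) * (r2 - target) <= 0) {
        bracket <- c(grid[i - 1], grid[i])
        rb <- c(r1, r2)
        break
      }
    }
  }
  if (is.null(bracket)) {
    # the target ratio is not achievable anywhere on the grid: fall
    # back to the mildest tethering that still produces a regurgitant
    # valve (the disease state the infarcted arm must represent), and
    # report the achieved ratio
    ok <- which(!vapply(vals, is.null, TRUE))
    gaps <- vapply(vals[ok], function(v) max(v$arm$valve$A_gap), 0)
    cand <- ok[gaps > 5]
    if (length(cand) == 0)
      stop("calibrate_pap_disp_scale: target ratio ", target,
           " not bracketed on [0, ", s_max,
           "] and no scale produces a regurgitant valve")
    pick <- vals[[min(cand)]]
    warning("calibrate_pap_disp_scale: target ratio ", target,
            " not achievable; achieved ", signif(pick$r, 4),
            " at the mildest regurgitant tethering (scale ",
            signif(pick$inf$pap_disp_scale_mm, 4), " mm)")
    out <- pick$inf
    attr(out, "achieved_ratio") <- pick$r
    attr(out, "arm") <- pick$arm
    return(out)
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rb[1]
  best <- NULL
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    vm <- ratio_at(mid)
    if (is.null(best) || abs(vm$r - target) < abs(best$r - target))
      best <- vm
    if (abs(vm$r - target) <= tol) break
    if ((r_lo - target) * (vm$r - target) <= 0) hi <- mid
    else { lo <- mid; r_lo <- vm$r }
  }
  out <- best$inf
  attr(out, "achieved_ratio") <- best$r
  attr(out, "arm") <- best$arm
  out
}
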