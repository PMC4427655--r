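#' Reduced-order left-ventricle geometry
#'
#' Transmurally lumped description of the left ventricle used by the
#' one-fiber pressure closure: a wall volume, an unloaded (stress-free)
#' cavity volume, and an effective long-axis/short-axis shape factor
#' used only to convert cavity volume into long-axis length.
#'
#' @param v_wall_ml wall volume (mL), > 0.
#' @param v_cav_ref_ml unloaded cavity volume (mL), > 0.
#' @param aspect effective long-semiaxis/short-semiaxis shape factor,
#'   > 0.  Values below one are admissible: the factor absorbs the
#'   difference between anatomical apex-base length and the cavity
#'   ellipsoid equivalent.
#' @return An object of class `ventricle_geometry`.
#' @export
ventricle_geometry <- function(v_wall_ml = 150, v_cav_ref_ml = 40,
                               aspect = 1) {
  if (!is.numeric(v_wall_ml) || v_wall_ml <= 0)
    stop("ventricle_geometry: v_wall_ml must be > 0")
  if (!is.numeric(v_cav_ref_ml) || v_cav_ref_ml <= 0)
    stop("ventricle_geometry: v_cav_ref_ml must be > 0")
  if (!is.numeric(aspect) || aspect <= 0)
    stop("ventricle_geometry: aspect must be > 0")
  structure(list(v_wall_ml = v_wall_ml, v_cav_ref_ml = v_cav_ref_ml,
                 aspect = aspect), class = "ventricle_geometry")
}

#' Infarct region
#'
#' An infarcted wall-volume fraction `phi` in which no active stress is
#' generated, together with the papillary-displacement coupling used by
#' the valve model: the posterior papillary tip is displaced
#' (apically and laterally, 2:1) by `phi * pap_disp_scale_mm`.
#'
#' @param phi infarcted fraction of the wall volume, in `[0, 0.6]`.
#' @param pap_disp_scale_mm papillary displacement magnitude per unit
#'   `phi` (mm), >= 0.
#' @return An object of class `infarct_region`.
#' @export
infarct_region <- function(phi = 0, pap_disp_scale_mm = 0) {
  if (!is.numeric(phi) || phi < 0 || phi > 0.6)
    stop("infarct_region: phi must be in [0, 0.6]")
  if (!is.numeric(pap_disp_scale_mm) || pap_disp_scale_mm < 0)
    stop("infarct_region: pap_disp_scale_mm must be >= 0")
  structure(list(phi = phi, pap_disp_scale_mm = pap_disp_scale_mm),
            class = "infarct_region")
}

#' Fiber stretch from cavity volume
#'
#' One-fiber kinematic closure: the myofiber stretch is the cube root
#' of the ratio of mid-wall volumes,
#' \eqn{\lambda_f = ((V + V_w/3)/(V_{ref} + V_w/3))^{1/3}}.
#'
#' @param geom a [ventricle_geometry()].
#' @param v_cav cavity volume (mL), > 0; vectorized.
#' @return Fiber stretch, 1 at the unloaded volume, strictly increasing
#'   in `v_cav`.
#' @export
fiber_stretch <- function(geom, v_cav) {
  stopifnot(inherits(geom, "ventricle_geometry"))
  if (any(v_cav <= 0)) stop("fiber_stretch: v_cav must be > 0")
  ((v_cav + geom$v_wall_ml / 3) /
     (geom$v_cav_ref_ml + geom$v_wall_ml / 3))^(1 / 3)
}

#' Passive fiber stress under uniaxial fiber extension
#'
#' Fiber-direction Cauchy stress of the myocardium law under isochoric
#' uniaxial fiber stretch \eqn{F = diag(\lambda, \lambda^{-1/2},
#' \lambda^{-1/2})} with the hydrostatic pressure eliminated by the
#' zero-transverse-stress condition, i.e.
#' \eqn{\sigma_f = \lambda\, d\hat\Psi/d\lambda} along the isochoric
#' path.
#'
#' @param params a [ho_params()].
#' @param lambda fiber stretch, > 0; vectorized.
#' @return Fiber Cauchy stress (kPa); zero at `lambda = 1`.
#' @export
passive_fiber_stress <- function(params, lambda) {
  stopifnot(inherits(params, "ho_params"))
  if (any(lambda <= 0)) stop("passive_fiber_stress: lambda must be > 0")
  I1 <- lambda^2 + 2 / lambda
  I4 <- lambda^2
  dI1 <- 2 * lambda - 2 / lambda^2
  dI4 <- 2 * lambda
  e4 <- pmax(I4 - 1, 0)
  dpsi <- vapply(seq_along(lambda), function(i) {
    .ho_dterm(params$a, params$b, I1[i] - 3) * dI1[i] +
      .ho_dterm(params$a_ff, params$b_ff, e4[i]^2) * 2 * e4[i] * dI4[i]
  }, numeric(1))
  lambda * dpsi
}

#' Cavity pressure from the one-fiber closure
#'
#' Total fiber stress is passive plus (1 - phi) times the active
#' tension; cavity pressure follows the thick-wall log closure
#' \eqn{P = (\sigma_f/3)\,\ln(1 + V_w/V)}.
#'
#' @param geom a [ventricle_geometry()].
#' @param params a [ho_params()].
#' @param act an [active_law()].
#' @param inf an [infarct_region()] (use `infarct_region(0)` when
#'   healthy).
#' @param t time within the cycle (s).
#' @param v_cav cavity volume (mL), > 0.
#' @return Cavity pressure (kPa); >= 0 whenever the total fiber stress
#'   is >= 0.
#' @export
cavity_pressure <- function(geom, params, act, inf, t, v_cav) {
  stopifnot(inherits(geom, "ventricle_geometry"),
            inherits(params, "ho_params"),
            inherits(act, "active_law"))
  phi <- if (is.null(inf)) 0 else inf$phi
  lam <- fiber_stretch(geom, v_cav)
  sig <- passive_fiber_stress(params, lam) +
    (1 - phi) * active_tension(act, t, lam)
  sig / 3 * log(1 + geom$v_wall_ml / v_cav)
}

#' Long-axis length from cavity volume
#'
#' Cavity-volume-equivalent ellipsoid long-axis length,
#' \eqn{L = 20\, \mathrm{aspect}^{2/3} (3V/(4\pi))^{1/3}} mm with `V` in
#' mL.  Long-axis shortening over a cycle is `L` at end-diastole minus
#' the cycle minimum of `L`.
#'
#' @param geom a [ventricle_geometry()].
#' @param v_cav cavity volume (mL), > 0; vectorized.
#' @return Long-axis length (mm), strictly increasing in `v_cav`.
#' @export
long_axis_length <- function(geom, v_cav) {
  stopifnot(inherits(geom, "ventricle_geometry"))
  if (any(v_cav <= 0)) stop("long_axis_length: v_cav must be > 0")
  20 * geom$aspect^(2 / 3) * (3 * v_cav / (4 * pi))^(1 / 3)
}

#' Ejection fraction
#'
#' @param edv,esv end-diastolic and end-systolic volumes (mL).
#' @return EF as a fraction, `(edv - esv)/edv`.
#' @export
#' @examples
#' round(100 * ejection_fraction(103, 83), 1)  # 19.4
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("ejection_fraction: edv must be > 0")
  (edv - esv) / edv
}

#' Size the infarct to a target ejection fraction
#'
#' Bisection on the infarcted wall fraction `phi` over `[0, 0.6]`:
#' the full cycle model ([run_cycle()]) is evaluated at each candidate
#' `phi` and the bracket is narrowed until the achieved EF is within
#' `tol` of `ef_target`.  EF is monotone non-increasing in `phi`, which
#' the bisection relies on.
#'
#' @param model a model configuration as returned by
#'   [study_config()]`$model` or assembled manually: a list with
#'   elements `geom`, `params`, `act`, `circ` (see [run_cycle()]).
#' @param ef_target target ejection fraction (fraction, e.g. `0.45`);
#'   must lie below the healthy (phi = 0) EF.
#' @param tol EF tolerance (fraction); default 0.0025 (= 0.25 EF
#'   percentage points).
#' @param pap_disp_scale_mm carried into the returned region.
#' @return An [infarct_region()] with the sized `phi`; attributes
#'   `ef_achieved` and `ef_healthy`.
#' @export
size_infarct <- function(model, ef_target, tol = 0.0025,
                         pap_disp_scale_mm = 0) {
  ef_at <- function(phi) {
    inf <- infarct_region(phi, pap_disp_scale_mm)
    run_cycle(model, infarct = inf)$EF
  }
  ef0 <- ef_at(0)
  if (abs(ef_target - ef0) <= tol) {
    out <- infarct_region(0, pap_disp_scale_mm)
    attr(out, "ef_achieved") <- ef0
    attr(out, "ef_healthy") <- ef0
    return(out)
  }
  if (ef_target >= ef0)
    stop("size_infarct: target EF ", signif(ef_target, 3),
         " not below the healthy EF ", signif(ef0, 3))
  lo <- 0; hi <- 0.6
  ef_hi <- ef_at(hi)
  if (ef_target < ef_hi - tol)
    stop("size_infarct: target EF ", signif(ef_target, 3),
         " unreachable; achievable EF range is [",
         signif(ef_hi, 3), ", ", signif(ef0, 3), "] for phi in [0, 0.6]")
  ef_mid <- ef0; mid <- 0
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    ef_mid <- ef_at(mid)
    if (abs(ef_mid - ef_target) <= tol && (hi - lo) < 0.02) break
    if (ef_mid > ef_target) lo <- mid else hi <- mid
  }
  out <- infarct_region(mid, pap_disp_scale_mm)
  attr(out, "ef_achieved") <- ef_mid
  attr(out, "ef_healthy") <- ef0
  out
}

#' Calibrate the healthy baseline
#'
#' Two-parameter calibration of the healthy model: the peak active
#' tension `T_max` is tuned (bisection) so the converged cycle's
#' ejection fraction matches `ef_target`, and the shape factor `aspect`
#' is then solved in closed form so the maximum long-axis shortening
#' matches `shortening_target_mm` (shortening scales exactly with
#' `aspect^(2/3)` while EF is independent of `aspect`, so the triangular
#' system is solved sequentially).
#'
#' @param model model configuration (list with `geom`, `params`, `act`,
#'   `circ`).
#' @param ef_target target healthy EF (fraction), default 0.55.
#' @param shortening_target_mm target maximum long-axis shortening,
#'   default 12.1 mm.
#' @param ef_tol EF tolerance (fraction), default 0.005 (0.5 points).
#' @param shortening_tol_mm shortening tolerance, default 0.2 mm.
#' @param t_max_bracket search bracket for `T_max` (kPa).
#' @return The calibrated model (same structure, updated `act$T_max`
#'   and `geom$aspect`) with attribute `healthy_cycle`, the converged
#'   [run_cycle()] result.
#' @export
calibrate_healthy <- function(model, ef_target = 0.55,
                              shortening_target_mm = 12.1,
                              ef_tol = 0.005, shortening_tol_mm = 0.2,
                              t_max_bracket = c(5, 400)) {
  # a crash (volume driven to zero) means the contraction is far too
  # strong for the load; treat as EF = 1 so the bisection backs off
  ef_at <- function(T_max) {
    m <- model
    m$act$T_max <- T_max
    tryCatch(run_cycle(m)$EF, error = function(e) 1)
  }
  lo <- t_max_bracket[1]; hi <- t_max_bracket[2]
  ef_lo <- ef_at(lo); ef_hi <- ef_at(hi)
  if (ef_target < ef_lo || ef_target > ef_hi)
    stop("calibrate_healthy: EF target ", ef_target,
         " outside achievable range [", signif(ef_lo, 3), ", ",
         signif(ef_hi, 3), "] for T_max in the bracket")
  T_mid <- lo
  for (i in 1:60) {
    T_mid <- (lo + hi) / 2
    ef_mid <- ef_at(T_mid)
    if (abs(ef_mid - ef_target) <= ef_tol / 4) break
    if (ef_mid < ef_target) lo <- T_mid else hi <- T_mid
  }
  model$act$T_max <- T_mid
  cyc <- run_cycle(model)
  # shortening is proportional to aspect^(2/3); solve exactly
  s1 <- cyc$shortening / model$geom$aspect^(2 / 3)
  model$geom$aspect <- (shortening_target_mm / s1)^(3 / 2)
  cyc <- run_cycle(model)
  if (abs(cyc$EF - ef_target) > ef_tol)
    warning("calibrate_healthy: EF missed tolerance: ", signif(cyc$EF, 4))
  if (abs(cyc$shortening - shortening_target_mm) > shortening_tol_mm)
    warning("calibrate_healthy: shortening missed tolerance: ",
            signif(cyc$shortening, 4))
  attr(model, "healthy_cycle") <- cyc
  model
}
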