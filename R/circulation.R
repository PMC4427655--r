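#' Lumped circulation parameters
#'
#' Two-state closure of the systemic circulation: a constant venous
#' filling pressure, diode mitral and aortic valves, and a single
#' arterial windkessel (compliance + peripheral resistance).  A mitral
#' regurgitant leak is modeled as a square-root orifice whose area is
#' supplied per time by the valve model.
#'
#' @param p_ven venous filling pressure (kPa).
#' @param r_mv mitral inflow resistance (kPa s/mL).
#' @param r_av aortic valve resistance (kPa s/mL).
#' @param c_art arterial compliance (mL/kPa).
#' @param r_per peripheral resistance (kPa s/mL).
#' @param p_art_init initial arterial pressure (kPa).
#' @param k_orifice regurgitant orifice coefficient
#'   (mL/s per mm^2 per sqrt(kPa)); the default follows a discharge
#'   coefficient of 0.6 with blood density 1060 kg/m^3.
#' @param period cardiac cycle period (s); heart rate 60 bpm by
#'   default.
#' @param dt integration time step (s).
#' @return An object of class `circulation_params`.
#' @export
circulation_params <- function(p_ven = 1.1, r_mv = 0.008, r_av = 0.006,
                               c_art = 12, r_per = 0.14,
                               p_art_init = 11, k_orifice = 0.82,
                               period = 1.0, dt = 0.001) {
  vals <- list(p_ven = p_ven, r_mv = r_mv, r_av = r_av, c_art = c_art,
               r_per = r_per, p_art_init = p_art_init,
               k_orifice = k_orifice, period = period, dt = dt)
  for (nm in c("r_mv", "r_av", "c_art", "r_per", "period", "dt"))
    if (!is.numeric(vals[[nm]]) || vals[[nm]] <= 0)
      stop("circulation_params: '", nm, "' must be > 0")
  if (k_orifice < 0) stop("circulation_params: k_orifice must be >= 0")
  structure(vals, class = "circulation_params")
}

# fast scalar cavity-pressure closure: returns function(t, V) -> kPa
.pressure_fun <- function(model, infarct = NULL) {
  g <- model$geom; p <- model$params; a <- model$act
  phi <- if (is.null(infarct)) 0 else infarct$phi
  vm3 <- g$v_wall_ml / 3
  den <- g$v_cav_ref_ml + vm3
  act_scale <- (1 - phi) * a$T_max
  function(t, V) {
    lam <- ((V + vm3) / den)^(1 / 3)
    I1 <- lam * lam + 2 / lam
    e4 <- max(lam * lam - 1, 0)
    dpsi <- if (p$a == 0) 0 else
      p$a / 2 * exp(p$b * (I1 - 3)) * (2 * lam - 2 / (lam * lam))
    if (p$a_ff > 0 && e4 > 0)
      dpsi <- dpsi + p$a_ff * exp(p$b_ff * e4 * e4) * e4 * 2 * lam
    sig <- lam * dpsi
    tau <- (t - a$t_act) / a$t_dur
    if (tau > 0 && tau < 1) {
      w <- sin(pi * tau)^2
      gl <- max(0, 1 + a$length_dep * (lam - 1))
      sig <- sig + act_scale * w * gl
    }
    sig / 3 * log(1 + g$v_wall_ml / V)
  }
}

#' One explicit integration step of the circulation
#'
#' Advances the coupled ventricle-circulation state by one explicit
#' Euler step.  Volume bookkeeping is exact:
#' `v_lv` changes by `(Q_in - Q_out - Q_reg) * dt`.
#'
#' @param state list with `t` (s), `v_lv` (mL), `p_art` (kPa).
#' @param model model configuration: list with `geom`
#'   ([ventricle_geometry()]), `params` ([ho_params()]), `act`
#'   ([active_law()]), `circ` ([circulation_params()]).
#' @param dt time step (s), > 0.
#' @param infarct optional [infarct_region()].
#' @param a_gap regurgitant orifice area at `state$t` (mm^2).
#' @return Updated state, with the flows used (`q_in`, `q_out`,
#'   `q_reg`, mL/s) and the ventricular pressure `p_lv` (kPa) attached.
#' @export
circulation_step <- function(state, model, dt, infarct = NULL, a_gap = 0) {
  if (dt <= 0) stop("circulation_step: dt must be > 0")
  cp <- model$circ
  pfun <- .pressure_fun(model, infarct)
  p_lv <- pfun(state$t, state$v_lv)
  q_in <- max(0, (cp$p_ven - p_lv) / cp$r_mv)
  q_out <- max(0, (p_lv - state$p_art) / cp$r_av)
  q_reg <- cp$k_orifice * a_gap * sqrt(max(0, p_lv - cp$p_ven))
  v_new <- state$v_lv + (q_in - q_out - q_reg) * dt
  p_art_new <- state$p_art + (q_out - state$p_art / cp$r_per) / cp$c_art * dt
  if (!is.finite(v_new) || v_new <= 0)
    stop("circulation_step: non-physical volume ", signif(v_new, 4),
         " mL at t = ", state$t)
  list(t = state$t + dt, v_lv = v_new, p_art = p_art_new,
       p_lv = p_lv, q_in = q_in, q_out = q_out, q_reg = q_reg)
}

#' Run cardiac cycles to the limit cycle
#'
#' Integrates the two-state circulation coupled to the one-fiber
#' ventricle over repeated cycles until the sampled volume trace
#' changes by less than 0.1 mL (max norm) between consecutive cycles,
#' or 50 cycles have elapsed.
#'
#' @param model model configuration (see [circulation_step()]).
#' @param infarct optional [infarct_region()]; scales active tension by
#'   `1 - phi`.
#' @param a_gap optional regurgitant orifice area: a single number
#'   (mm^2) or a function of time within the cycle returning mm^2.
#' @param v_init optional initial cavity volume (mL).
#' @return An object of class `cycle_result`: time series `t`, `V_lv`,
#'   `P_lv`, `P_art`, `L`, `Q_reg` over the final cycle plus scalars
#'   `EDV`, `ESV`, `EF` (fraction), `shortening` (mm),
#'   `regurgitant_volume` (mL/beat), `n_cycles`, and `converged`.
#' @export
run_cycle <- function(model, infarct = NULL, a_gap = NULL, v_init = NULL) {
  cp <- model$circ
  stopifnot(inherits(cp, "circulation_params"))
  pfun <- .pressure_fun(model, infarct)
  gap_fun <- if (is.null(a_gap)) function(t) 0
             else if (is.function(a_gap)) a_gap
             else function(t) a_gap
  n <- round(cp$period / cp$dt)
  dt <- cp$period / n
  v <- if (is.null(v_init)) 2 * model$geom$v_cav_ref_ml else v_init
  p_art <- cp$p_art_init
  prev_trace <- NULL
  converged <- FALSE
  n_cycles <- 0L
  tgrid <- (seq_len(n) - 1) * dt
  gap_t <- vapply(tgrid, gap_fun, numeric(1))
  V <- P <- PA <- QR <- numeric(n)
  for (cyc in 1:50) {
    n_cycles <- cyc
    for (i in seq_len(n)) {
      t <- tgrid[i]
      p_lv <- pfun(t, v)
      q_in <- max(0, (cp$p_ven - p_lv) / cp$r_mv)
      q_out <- max(0, (p_lv - p_art) / cp$r_av)
      q_reg <- cp$k_orifice * gap_t[i] * sqrt(max(0, p_lv - cp$p_ven))
      V[i] <- v; P[i] <- p_lv; PA[i] <- p_art; QR[i] <- q_reg
      v_new <- v + (q_in - q_out - q_reg) * dt
      if (!is.finite(v_new))
        stop("run_cycle: non-finite volume at t = ", t, " in cycle ", cyc)
      # numerical floor: an extreme leak cannot drain the cavity past
      # the trabecular residuum within one step
      if (v_new < 1) v_new <- 1
      v <- v_new
      p_art <- p_art + (q_out - p_art / cp$r_per) / cp$c_art * dt
    }
    if (!is.null(prev_trace) && max(abs(V - prev_trace)) < 0.1) {
      converged <- TRUE
      break
    }
    prev_trace <- V
  }
  L <- long_axis_length(model$geom, V)
  edv <- max(V); esv <- min(V)
  structure(list(
    t = tgrid, V_lv = V, P_lv = P, P_art = PA, L = L, Q_reg = QR,
    EDV = edv, ESV = esv,
    EF = ejection_fraction(edv, esv),
    shortening = long_axis_length(model$geom, edv) - min(L),
    regurgitant_volume = sum(QR) * dt,
    n_cycles = n_cycles, dt = dt, converged = converged
  ), class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result> EDV =", signif(x$EDV, 4), "mL  ESV =",
      signif(x$ESV, 4), "mL  EF =", signif(100 * x$EF, 4),
      "%  shortening =", signif(x$shortening, 3), "mm\n",
      " regurgitant volume =", signif(x$regurgitant_volume, 3),
      "mL/beat  cycles =", x$n_cycles,
      " converged =", x$converged, "\n")
  invisible(x)
}

#' Compare two cardiac cycles
#'
#' Tabulates the differences (variant minus baseline) in the scalar
#' cycle outcomes and returns overlay-ready PV-loop data.
#'
#' @param baseline,variant converged [run_cycle()] results.
#' @return List with `deltas` (named numeric: `EDV`, `ESV`, `EF_points`
#'   in EF percentage points, `peak_pressure` kPa, `regurgitant_volume`
#'   mL) and `overlay` (data.frame of both loops, column `which`).
#' @export
compare_cycles <- function(baseline, variant) {
  stopifnot(inherits(baseline, "cycle_result"),
            inherits(variant, "cycle_result"))
  if (!baseline$converged || !variant$converged)
    stop("compare_cycles: both cycles must be converged")
  deltas <- c(
    EDV = variant$EDV - baseline$EDV,
    ESV = variant$ESV - baseline$ESV,
    EF_points = 100 * (variant$EF - baseline$EF),
    peak_pressure = max(variant$P_lv) - max(baseline$P_lv),
    regurgitant_volume = variant$regurgitant_volume -
      baseline$regurgitant_volume
  )
  overlay <- rbind(
    data.frame(t = baseline$t, V = baseline$V_lv, P = baseline$P_lv,
               which = "baseline"),
    data.frame(t = variant$t, V = variant$V_lv, P = variant$P_lv,
               which = "variant"))
  list(deltas = deltas, overlay = overlay)
}
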