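#' One-dimensional exponential material law
#'
#' Two-parameter exponential true-stress law
#' \eqn{\sigma(\varepsilon) = A(e^{B\varepsilon} - 1)} used for mitral
#' leaflet (circumferential / radial) and chordae (basal / marginal)
#' tissue.  Chordae variants are tension-only: compressive (negative)
#' strain carries zero stress.
#'
#' @param A scale (kPa), `A >= 0`.
#' @param B exponent (dimensionless), `B > 0`.
#' @param tension_only logical; floor the stress at zero for negative
#'   strain (chordae behavior).
#' @return An object of class `exp_law`.
#' @export
#' @examples
#' stress_1d(exp_law(1, 10), 0.1)   # = exp(1) - 1
exp_law <- function(A, B, tension_only = FALSE) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0)
    stop("exp_law: A must be a single finite number >= 0")
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B <= 0)
    stop("exp_law: B must be a single finite number > 0")
  structure(list(A = A, B = B, tension_only = isTRUE(tension_only)),
            class = "exp_law")
}

#' @rdname exp_law
#' @param law an `exp_law` object.
#' @param strain true (logarithmic) strain, scalar or vector.
#' @return `stress_1d`: true stress in kPa, vectorized over `strain`;
#'   zero at zero strain, monotone increasing and convex for
#'   `strain >= 0`.
#' @export
stress_1d <- function(law, strain) {
  stopifnot(inherits(law, "exp_law"))
  s <- law$A * (exp(law$B * strain) - 1)
  if (law$tension_only) s <- pmax(s, 0)
  s
}

# stress law used by the strip solver for leaflet cables: exponential
# in tension with a linear (initial-tangent) branch in compression,
# C1-continuous at zero strain
.stress_1d_solver <- function(law, strain) {
  s <- law$A * (exp(law$B * pmax(strain, 0)) - 1)
  if (!law$tension_only) s <- s + law$A * law$B * pmin(strain, 0)
  s
}

# chordae stress for the equilibrium solver: the tension-only law with
# a C1 cubic blend on [0, eps_s] so the slack/taut transition has no
# slope discontinuity (Newton would chatter on the kink); outside the
# blend zone it is exactly the tension-only law
.chord_stress_solver <- function(law, strain, eps_s = 0.01) {
  if (strain <= 0) return(0)
  if (strain >= eps_s) return(law$A * (exp(law$B * strain) - 1))
  ss <- law$A * (exp(law$B * eps_s) - 1)
  ds <- law$A * law$B * exp(law$B * eps_s)
  tt <- strain / eps_s
  # Hermite: value 0, slope 0 at 0; value ss, slope ds at eps_s
  (3 * tt^2 - 2 * tt^3) * ss + (tt^3 - tt^2) * ds * eps_s
}

#' Active fiber-tension law
#'
#' Prescribed activation waveform that stands in for the
#' electromechanics of the full simulator: a squared-sine pulse in time
#' with a linear fiber-length dependence,
#' \eqn{T(t,\lambda) = T_{max}\, w(t)\, g(\lambda)} with
#' \eqn{w(t) = \sin^2(\pi (t - t_{act})/t_{dur})} inside the activation
#' window and zero outside, and
#' \eqn{g(\lambda) = \max(0,\, 1 + c(\lambda - 1))}.
#'
#' @param T_max peak active fiber tension (kPa).
#' @param t_act activation onset within the cycle (s).
#' @param t_dur activation duration (s), `0 < t_dur`.
#' @param length_dep slope `c` of the linear length dependence.
#' @return An object of class `active_law`.
#' @export
active_law <- function(T_max = 110, t_act = 0, t_dur = 0.4,
                       length_dep = 6) {
  if (!is.numeric(T_max) || T_max < 0) stop("active_law: T_max must be >= 0")
  if (!is.numeric(t_dur) || t_dur <= 0) stop("active_law: t_dur must be > 0")
  structure(list(T_max = T_max, t_act = t_act, t_dur = t_dur,
                 length_dep = length_dep), class = "active_law")
}

#' @rdname active_law
#' @param law an `active_law` object.
#' @param t time within the cycle (s).
#' @param fiber_stretch current fiber stretch \eqn{\lambda}.
#' @return `active_tension`: active fiber Cauchy stress (kPa), >= 0.
#' @export
active_tension <- function(law, t, fiber_stretch = 1) {
  stopifnot(inherits(law, "active_law"))
  tau <- (t - law$t_act) / law$t_dur
  w <- ifelse(tau > 0 & tau < 1, sin(pi * tau)^2, 0)
  g <- pmax(0, 1 + law$length_dep * (fiber_stretch - 1))
  law$T_max * w * g
}
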