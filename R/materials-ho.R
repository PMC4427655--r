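#' Passive myocardium material parameters
#'
#' Constructs the parameter set of the orthotropic exponential
#' (Holzapfel--Ogden-type) strain-energy function used for passive
#' myocardium.  The default values are the transversely isotropic set
#' used throughout the package: only the isotropic and fiber terms are
#' active, the sheet and fiber-sheet terms vanish.
#'
#' @param k bulk penalty modulus (kPa); enforces near-incompressibility.
#' @param a,b isotropic scale (kPa) and exponent (dimensionless).
#' @param a_ff,b_ff fiber scale (kPa) and exponent.
#' @param a_ss,b_ss sheet scale (kPa) and exponent.
#' @param a_fs,b_fs fiber-sheet coupling scale (kPa) and exponent.
#'
#' @return An object of class `ho_params`.
#' @export
#' @examples
#' p <- ho_params()
#' p$a_ff
ho_params <- function(k = 1000, a = 0.33, b = 7.08,
                      a_ff = 0.25, b_ff = 5.34,
                      a_ss = 0, b_ss = 0,
                      a_fs = 0, b_fs = 0) {
  p <- list(k = k, a = a, b = b, a_ff = a_ff, b_ff = b_ff,
            a_ss = a_ss, b_ss = b_ss, a_fs = a_fs, b_fs = b_fs)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("ho_params: '", nm, "' must be a single finite non-negative number")
  }
  structure(p, class = "ho_params")
}

#' Deformation state for the myocardium law
#'
#' Bundles a deformation gradient with the local orthonormal material
#' frame (fiber, sheet, sheet-normal) in which the anisotropic
#' invariants are evaluated.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param f0,s0,n0 unit reference fiber / sheet / normal directions;
#'   must be mutually orthonormal.
#'
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(F,
                              f0 = c(1, 0, 0),
                              s0 = c(0, 1, 0),
                              n0 = c(0, 0, 1)) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || !all(is.finite(F)))
    stop("deformation_state: F must be a finite 3x3 matrix")
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("deformation_state: det(F) must be positive (got ", signif(J, 6), ")")
  Q <- cbind(f0, s0, n0)
  if (max(abs(crossprod(Q) - diag(3))) > 1e-8)
    stop("deformation_state: f0, s0, n0 must be mutually orthonormal")
  structure(list(F = F, f0 = as.numeric(f0), s0 = as.numeric(s0),
                 n0 = as.numeric(n0)), class = "deformation_state")
}

# exponential energy term a/(2b)*(exp(b*x)-1), with the scale-zero and
# exponent-zero limits handled without 0/0
.ho_term <- function(a, b, x) {
  if (a == 0) return(0)
  if (b == 0) return(a * x / 2)
  a / (2 * b) * (exp(b * x) - 1)
}

# derivative of .ho_term with respect to x
.ho_dterm <- function(a, b, x) {
  if (a == 0) return(0)
  a / 2 * exp(b * x)
}

.ho_invariants <- function(state) {
  F <- state$F
  C <- crossprod(F)                      # F^T F
  list(
    I1 = sum(diag(C)),
    I4f = as.numeric(state$f0 %*% C %*% state$f0),
    I4s = as.numeric(state$s0 %*% C %*% state$s0),
    I8fs = as.numeric(state$f0 %*% C %*% state$s0),
    J = det(F)
  )
}

#' Strain-energy density of passive myocardium
#'
#' Orthotropic exponential energy on the full invariants
#' \deqn{\Psi = \frac{a}{2b}(e^{b(I_1-3-2\ln J)}-1)
#'   + \sum_{i \in \{ff,ss\}} \frac{a_i}{2b_i}(e^{b_i \langle I_{4i}-1\rangle^2}-1)
#'   + \frac{a_{fs}}{2b_{fs}}(e^{b_{fs} I_{8fs}^2}-1)
#'   + \frac{k}{2}(\ln J)^2}
#' with \eqn{\langle x \rangle = \max(x, 0)} so the fiber and sheet
#' terms are tension-only, and any term with a zero scale contributing
#' exactly zero.  The \eqn{-2\ln J} correction in the isotropic
#' exponent is the standard compressible form that makes the reference
#' configuration stress-free (without it the Cauchy stress at
#' \eqn{F = I} would be \eqn{a I}); on isochoric motions it changes
#' nothing.
#'
#' @param params a [ho_params()] object.
#' @param state a [deformation_state()] object.
#' @return Energy density in kPa; zero at the identity and at any pure
#'   rotation.
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "ho_params"), inherits(state, "deformation_state"))
  iv <- .ho_invariants(state)
  e4f <- max(iv$I4f - 1, 0)
  e4s <- max(iv$I4s - 1, 0)
  .ho_term(params$a, params$b, iv$I1 - 3 - 2 * log(iv$J)) +
    .ho_term(params$a_ff, params$b_ff, e4f^2) +
    .ho_term(params$a_ss, params$b_ss, e4s^2) +
    .ho_term(params$a_fs, params$b_fs, iv$I8fs^2) +
    params$k / 2 * log(iv$J)^2
}

#' Cauchy (true) stress of passive myocardium
#'
#' Computes \eqn{\sigma = J^{-1} (\partial\Psi/\partial F) F^T} from the
#' analytic first Piola derivative of [strain_energy()].
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress tensor (kPa); zero at the
#'   identity.
#' @export
cauchy_stress <- function(params, state) {
  stopifnot(inherits(params, "ho_params"), inherits(state, "deformation_state"))
  F <- state$F
  f0 <- state$f0; s0 <- state$s0
  iv <- .ho_invariants(state)
  e4f <- max(iv$I4f - 1, 0)
  e4s <- max(iv$I4s - 1, 0)

  # dPsi/dx coefficients of each invariant-valued term
  c1 <- .ho_dterm(params$a, params$b,
                  iv$I1 - 3 - 2 * log(iv$J))                # w.r.t. I1
  c4f <- .ho_dterm(params$a_ff, params$b_ff, e4f^2) * 2 * e4f
  c4s <- .ho_dterm(params$a_ss, params$b_ss, e4s^2) * 2 * e4s
  c8 <- .ho_dterm(params$a_fs, params$b_fs, iv$I8fs^2) * 2 * iv$I8fs

  Ff <- F %*% f0
  Fs <- F %*% s0
  Finv_t <- t(solve(F))
  P <- 2 * c1 * (F - Finv_t) +
    2 * c4f * tcrossprod(Ff, f0) +
    2 * c4s * tcrossprod(Fs, s0) +
    c8 * (tcrossprod(Ff, s0) + tcrossprod(Fs, f0)) +
    params$k * log(iv$J) * Finv_t
  sig <- (P %*% t(F)) / iv$J
  (sig + t(sig)) / 2
}

#' Virtual simple-shear test
#'
#' Applies simple shear in the material frame and records the
#' work-conjugate shear component of the Cauchy stress against the
#' applied shear amount.  Mode `"XY"` imposes
#' \eqn{F = I + \gamma\, e_Y \otimes e_X}: material lines along axis X
#' tilt toward axis Y, so modes `FN` and `FS` stretch the fiber
#' direction.  The abscissa of the returned curve is \eqn{\gamma}
#' itself (the true shear strain convention used for these plots).
#'
#' @param params a [ho_params()] object.
#' @param mode one of `"FN", "FS", "NF", "NS", "SF", "SN"`.
#' @param gammas non-negative, increasing shear amounts.
#' @return A [stress_strain_curve()] with the mode label.
#' @export
#' @examples
#' shear_test(ho_params(), "FS", seq(0, 0.5, by = 0.1))
shear_test <- function(params, mode, gammas) {
  modes <- c("FN", "FS", "NF", "NS", "SF", "SN")
  if (!(is.character(mode) && length(mode) == 1L && mode %in% modes))
    stop("shear_test: unknown mode '", paste(mode, collapse = ","),
         "'; must be one of ", paste(modes, collapse = ", "))
  if (any(gammas < 0) || (length(gammas) > 1L && any(diff(gammas) <= 0)))
    stop("shear_test: gammas must be non-negative and increasing")
  axes <- list(F = 1L, S = 2L, N = 3L)
  iX <- axes[[substr(mode, 1, 1)]]
  iY <- axes[[substr(mode, 2, 2)]]
  stress <- vapply(gammas, function(g) {
    F <- diag(3)
    F[iY, iX] <- F[iY, iX] + g
    st <- deformation_state(F)
    sig <- cauchy_stress(params, st)
    sig[iX, iY]
  }, numeric(1))
  stress_strain_curve(mode, strain = gammas, stress = stress)
}
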