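#' Material-fitting problem
#'
#' Describes a bounded least-squares fit of constitutive parameters to
#' one or more measured stress-strain curves.  Two law families are
#' supported: `"exp1d"` (one [exp_law()] per curve mode, parameters
#' named `A_<mode>`, `B_<mode>`, or plain `A`, `B` when all curves share
#' one mode) and `"HO-shear"` (the myocardium law probed by
#' [shear_test()] in each curve's shear mode; parameters are the
#' [ho_params()] field names).
#'
#' @param curves list of [stress_strain_curve()] objects (at least one).
#' @param law `"exp1d"` or `"HO-shear"`.
#' @param free_params character vector of parameter names to fit.
#' @param bounds named list of `c(lo, hi)` per free parameter; finite,
#'   `lo < hi`.
#' @param init named numeric vector of start values (within bounds).
#' @param fixed named list of non-fitted parameter values (defaults:
#'   printed myocardium set for `"HO-shear"`; none needed for
#'   `"exp1d"`).
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(curves, law = c("exp1d", "HO-shear"),
                        free_params, bounds, init, fixed = list()) {
  law <- match.arg(law)
  if (inherits(curves, "stress_strain_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("fit_problem: at least one curve required")
  ok <- vapply(curves, inherits, logical(1), "stress_strain_curve")
  if (!all(ok)) stop("fit_problem: curves must be stress_strain_curve objects")
  shear_modes <- c("FN", "FS", "NF", "NS", "SF", "SN")
  for (cu in curves) {
    m <- attr(cu, "mode")
    if (law == "HO-shear" && !(m %in% shear_modes))
      stop("fit_problem: curve mode '", m, "' is not a shear mode")
    if (law == "exp1d" && m %in% shear_modes)
      stop("fit_problem: shear-mode curve '", m, "' needs law 'HO-shear'")
  }
  free_params <- as.character(free_params)
  if (length(free_params) < 1L) stop("fit_problem: no free parameters")
  for (p in free_params) {
    bd <- bounds[[p]]
    if (is.null(bd) || length(bd) != 2L || !all(is.finite(bd)) || bd[1] >= bd[2])
      stop("fit_problem: parameter '", p, "' needs finite bounds lo < hi")
    x0 <- init[[p]]
    if (is.null(x0) || !is.finite(x0))
      stop("fit_problem: parameter '", p, "' needs a finite start value")
    if (x0 < bd[1] || x0 > bd[2])
      stop("fit_problem: start value for '", p, "' outside bounds")
  }
  structure(list(curves = curves, law = law, free_params = free_params,
                 bounds = bounds, init = init, fixed = fixed),
            class = "fit_problem")
}

# merge free params into the full parameter vector a law needs
.fit_full_params <- function(problem, params) {
  params <- as.list(params)
  out <- problem$fixed
  out[names(params)] <- params
  out
}

# stacked residual vector (measured - predicted) across all curves
.fit_residuals <- function(problem, params) {
  full <- .fit_full_params(problem, params)
  unlist(lapply(problem$curves, function(cu) {
    m <- attr(cu, "mode")
    pred <- if (problem$law == "exp1d") {
      A <- full[[paste0("A_", m)]]; B <- full[[paste0("B_", m)]]
      if (is.null(A)) A <- full[["A"]]
      if (is.null(B)) B <- full[["B"]]
      if (is.null(A) || is.null(B))
        stop("objective: missing A/B parameters for mode '", m, "'")
      stress_1d(exp_law(max(A, 0), max(B, 1e-12)), cu$strain)
    } else {
      defaults <- unclass(ho_params())
      hp <- defaults
      hp[names(full)[names(full) %in% names(defaults)]] <-
        full[names(full) %in% names(defaults)]
      hp <- do.call(ho_params, lapply(hp, function(v) max(v, 0)))
      shear_test(hp, m, cu$strain)$stress
    }
    cu$stress - pred
  }), use.names = FALSE)
}

#' Least-squares objective
#'
#' Sum of squared differences between measured and predicted stresses
#' at the measured strains, summed over all curves of the problem.
#'
#' @param problem a [fit_problem()].
#' @param params named numeric vector of the free parameter values.
#' @return Scalar sum of squared residuals (kPa^2).
#' @export
objective <- function(problem, params) {
  stopifnot(inherits(problem, "fit_problem"))
  sum(.fit_residuals(problem, params)^2)
}

#' Fit material parameters to stress-strain curves
#'
#' Bounded Levenberg--Marquardt least squares
#' (via [minpack.lm::nls.lm()]) on the stacked stress residuals.  The
#' fit is fully deterministic: identical inputs give identical results.
#'
#' @param problem a [fit_problem()].
#' @param max_evals maximum objective evaluations before giving up
#'   (best-so-far parameters are still returned, flagged unconverged).
#' @return An object of class `fit_result`: list with `params` (named
#'   vector), `sse`, `n_points`, `converged`, `n_evals`.
#' @export
#' @examples
#' law <- exp_law(2, 12)
#' cu <- stress_strain_curve("basal", seq(0, 0.3, length.out = 30),
#'                           stress_1d(law, seq(0, 0.3, length.out = 30)))
#' pr <- fit_problem(list(cu), "exp1d", c("A", "B"),
#'                   bounds = list(A = c(0, 100), B = c(0.1, 100)),
#'                   init = c(A = 1, B = 5))
#' fit(pr)$params
fit <- function(problem, max_evals = 10000) {
  stopifnot(inherits(problem, "fit_problem"))
  lo <- vapply(problem$free_params, function(p) problem$bounds[[p]][1], 0)
  hi <- vapply(problem$free_params, function(p) problem$bounds[[p]][2], 0)
  x0 <- vapply(problem$free_params, function(p) problem$init[[p]], 0)
  names(x0) <- problem$free_params
  res <- minpack.lm::nls.lm(
    par = x0,
    lower = lo, upper = hi,
    fn = function(p) {
      names(p) <- problem$free_params
      .fit_residuals(problem, p)
    },
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxfev = max_evals, maxiter = 1000))
  pars <- res$par
  names(pars) <- problem$free_params
  n_pts <- sum(vapply(problem$curves, nrow, 0L))
  structure(list(
    params = unlist(pars),
    sse = sum(res$fvec^2),
    n_points = n_pts,
    converged = res$info %in% 1:4,
    n_evals = res$niter,
    message = res$message
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> converged =", x$converged,
      " sse =", signif(x$sse, 6), " (", x$n_points, "points )\n")
  print(signif(x$params, 6))
  invisible(x)
}

#' Generate synthetic stress-strain fixtures
#'
#' Emulates the experimental leaflet and chordae data the material laws
#' are fitted to: exponential-type, monotone, convex true-stress curves
#' with optional additive Gaussian noise.  Reproducible under `seed`;
#' the generating parameters and seed are stored in each curve's
#' metadata.
#'
#' @param law `"exp1d"` or `"HO-shear"`.
#' @param true_params for `"exp1d"`: named list of [exp_law()] objects,
#'   one per curve, names = curve modes; for `"HO-shear"`: a named list
#'   with an [ho_params()] object under `params` and a character vector
#'   of shear modes under `modes`.
#' @param strains strain sample points (shared by all curves).
#' @param noise_sd standard deviation of additive stress noise (kPa),
#'   `>= 0`.
#' @param seed integer RNG seed.
#' @return List of [stress_strain_curve()] objects.
#' @export
generate_synthetic_curves <- function(law = c("exp1d", "HO-shear"),
                                      true_params, strains,
                                      noise_sd = 0, seed = 1L) {
  law <- match.arg(law)
  if (noise_sd < 0) stop("generate_synthetic_curves: noise_sd must be >= 0")
  set.seed(as.integer(seed))
  if (law == "exp1d") {
    out <- lapply(names(true_params), function(m) {
      lw <- true_params[[m]]
      stopifnot(inherits(lw, "exp_law"))
      s <- stress_1d(lw, strains) + stats::rnorm(length(strains), 0, noise_sd)
      stress_strain_curve(m, strains, s,
                          meta = list(true_params = c(A = lw$A, B = lw$B),
                                      seed = seed, noise_sd = noise_sd))
    })
    names(out) <- names(true_params)
    out
  } else {
    hp <- true_params$params
    stopifnot(inherits(hp, "ho_params"))
    out <- lapply(true_params$modes, function(m) {
      cu <- shear_test(hp, m, strains)
      s <- cu$stress + stats::rnorm(length(strains), 0, noise_sd)
      stress_strain_curve(m, strains, s,
                          meta = list(true_params = unlist(unclass(hp)),
                                      seed = seed, noise_sd = noise_sd))
    })
    names(out) <- true_params$modes
    out
  }
}

#' Default leaflet and chordae material laws
#'
#' The package's default mitral tissue parameters: the leaflet is
#' stiffer circumferentially than radially and the chordae are stiffer
#' marginally than basally (at 10% true strain), matching the
#' qualitative shape of published porcine leaflet and chordae data.
#'
#' @return Named list of [exp_law()] objects with elements
#'   `circumferential`, `radial`, `basal`, `marginal` (chordae laws are
#'   tension-only).
#' @export
default_tissue_laws <- function() {
  list(
    circumferential = exp_law(1.5, 25),
    radial = exp_law(1.0, 15),
    basal = exp_law(120, 30, tension_only = TRUE),
    marginal = exp_law(60, 45, tension_only = TRUE)
  )
}

#' Fit the default tissue laws from synthetic fixtures
#'
#' Convenience wrapper used by the study pipeline: generates synthetic
#' leaflet and chordae curves from [default_tissue_laws()] and fits an
#' [exp_law()] to each, returning the fitted laws.
#'
#' @param strains optional strain grid for the fixtures; by default
#'   each tissue uses its experiment's range (leaflets to 0.30,
#'   chordae to 0.12 true strain, 30 points).
#' @param noise_sd additive stress noise, as a fraction of each curve's
#'   peak stress.
#' @param seed RNG seed for the fixture generator.
#' @return Named list of fitted [exp_law()] objects (same names as
#'   [default_tissue_laws()]), with attribute `"fits"` holding the
#'   [fit()] results.
#' @export
fit_tissue_laws <- function(strains = NULL, noise_sd = 0.02, seed = 1L) {
  truth <- default_tissue_laws()
  # measurement ranges of the emulated experiments: leaflet tissue is
  # tested to large strain, chordae only to ~12% (they are far stiffer)
  ranges <- list(circumferential = 0.30, radial = 0.30,
                 basal = 0.12, marginal = 0.12)
  fits <- list()
  laws <- list()
  for (m in names(truth)) {
    str_m <- if (is.null(strains)) seq(0, ranges[[m]], length.out = 30)
             else strains
    peak <- max(stress_1d(truth[[m]], str_m))
    cu <- generate_synthetic_curves(
      "exp1d", truth[m], str_m, noise_sd = noise_sd * peak,
      seed = seed + match(m, names(truth)))
    pr <- fit_problem(cu, "exp1d", c("A", "B"),
                      bounds = list(A = c(1e-6, 1e4), B = c(0.5, 200)),
                      init = c(A = truth[[m]]$A * 2, B = truth[[m]]$B * 0.5))
    ft <- fit(pr)
    fits[[m]] <- ft
    laws[[m]] <- exp_law(ft$params[["A"]], ft$params[["B"]],
                         tension_only = truth[[m]]$tension_only)
  }
  attr(laws, "fits") <- fits
  laws
}
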