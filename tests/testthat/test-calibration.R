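test_that("objective is the stated least-squares functional (hand-computed case)", {
  # three points, A = 2, B = 5 predictions computed by hand:
  # sigma_hat(0.1) = 2(e^0.5 - 1), sigma_hat(0.2) = 2(e^1 - 1),
  # sigma_hat(0.3) = 2(e^1.5 - 1)
  meas <- c(1.5, 3.0, 7.0)
  cu <- stress_strain_curve("basal", c(0.1, 0.2, 0.3), meas)
  pr <- fit_problem(cu, "exp1d", c("A", "B"),
                    bounds = list(A = c(0, 10), B = c(0.1, 20)),
                    init = c(A = 2, B = 5))
  pred <- 2 * (exp(5 * c(0.1, 0.2, 0.3)) - 1)
  expect_equal(objective(pr, c(A = 2, B = 5)), sum((meas - pred)^2),
               tolerance = 1e-12)
  # single point: sse = squared residual by definition
  one <- stress_strain_curve("basal", 0.1, 1.5)
  pr1 <- fit_problem(one, "exp1d", c("A", "B"),
                     bounds = list(A = c(0, 10), B = c(0.1, 20)),
                     init = c(A = 2, B = 5))
  expect_equal(objective(pr1, c(A = 2, B = 5)),
               (1.5 - 2 * (exp(0.5) - 1))^2, tolerance = 1e-12)
})

test_that("objective is zero on self-generated data and rises when perturbed", {
  eps <- seq(0, 0.3, length.out = 20)
  truth <- exp_law(2, 12)
  cu <- stress_strain_curve("marginal", eps, stress_1d(truth, eps))
  pr <- fit_problem(cu, "exp1d", c("A", "B"),
                    bounds = list(A = c(0, 100), B = c(1, 50)),
                    init = c(A = 2, B = 12))
  expect_equal(objective(pr, c(A = 2, B = 12)), 0, tolerance = 1e-18)
  expect_gt(objective(pr, c(A = 2.2, B = 12)), 0)
})

test_that("noiseless exp1d parameters are recovered within 1%", {
  eps <- seq(0, 0.3, length.out = 30)
  truth <- exp_law(2, 12)
  cu <- stress_strain_curve("basal", eps, stress_1d(truth, eps))
  pr <- fit_problem(cu, "exp1d", c("A", "B"),
                    bounds = list(A = c(1e-3, 100), B = c(1, 60)),
                    init = c(A = 0.5, B = 6))
  res <- fit(pr)
  expect_true(res$converged)
  expect_equal(unname(res$params["A"]), 2, tolerance = 0.01)
  expect_equal(unname(res$params["B"]), 12, tolerance = 0.01)
  expect_lt(res$sse, 1e-8)
})

test_that("noiseless myocardium shear parameters are recovered within 2%", {
  g <- seq(0.02, 0.5, length.out = 15)
  truth <- ho_params()
  curves <- list(shear_test(truth, "FN", g), shear_test(truth, "FS", g))
  pr <- fit_problem(curves, "HO-shear",
                    free_params = c("a", "b", "a_ff", "b_ff"),
                    bounds = list(a = c(0.01, 5), b = c(1, 20),
                                  a_ff = c(0.01, 5), b_ff = c(1, 20)),
                    init = c(a = 0.8, b = 4, a_ff = 0.6, b_ff = 3))
  res <- fit(pr)
  expect_true(res$converged)
  expect_equal(unname(res$params["a"]), 0.33, tolerance = 0.02)
  expect_equal(unname(res$params["b"]), 7.08, tolerance = 0.02)
  expect_equal(unname(res$params["a_ff"]), 0.25, tolerance = 0.02)
  expect_equal(unname(res$params["b_ff"]), 5.34, tolerance = 0.02)
})

test_that("all-zero stresses drive the scale to its lower bound", {
  eps <- seq(0, 0.3, length.out = 20)
  cu <- stress_strain_curve("basal", eps, rep(0, 20))
  pr <- fit_problem(cu, "exp1d", c("A", "B"),
                    bounds = list(A = c(0, 100), B = c(1, 50)),
                    init = c(A = 1, B = 10))
  res <- fit(pr)
  expect_equal(unname(res$params["A"]), 0, tolerance = 1e-8)
})

test_that("fitting is deterministic: repeated runs are identical", {
  eps <- seq(0, 0.25, length.out = 25)
  cu <- generate_synthetic_curves("exp1d", list(basal = exp_law(3, 15)),
                                  eps, noise_sd = 0.5, seed = 99)
  pr <- fit_problem(cu, "exp1d", c("A", "B"),
                    bounds = list(A = c(1e-3, 100), B = c(1, 60)),
                    init = c(A = 1, B = 8))
  expect_identical(fit(pr)$params, fit(pr)$params)
})

test_that("synthetic curves: exactness without noise, reproducibility with", {
  eps <- seq(0, 0.3, length.out = 15)
  truth <- list(circumferential = exp_law(1.5, 25))
  c0 <- generate_synthetic_curves("exp1d", truth, eps, noise_sd = 0,
                                  seed = 3)
  expect_equal(c0[[1]]$stress, stress_1d(truth[[1]], eps),
               tolerance = 1e-12)
  c1 <- generate_synthetic_curves("exp1d", truth, eps, noise_sd = 1,
                                  seed = 5)
  c2 <- generate_synthetic_curves("exp1d", truth, eps, noise_sd = 1,
                                  seed = 5)
  expect_identical(c1[[1]]$stress, c2[[1]]$stress)
  expect_false(identical(c0[[1]]$stress, c1[[1]]$stress))
  meta <- attr(c1[[1]], "meta")
  expect_equal(unname(meta$true_params["B"]), 25)
  expect_equal(meta$seed, 5)
})

test_that("Monte-Carlo recovery of the exponent under noise succeeds in >= 18/20 seeds", {
  eps <- seq(0, 0.3, length.out = 50)
  truth <- list(basal = exp_law(2, 12))
  peak <- max(stress_1d(truth$basal, eps))
  hits <- 0
  for (seed in 1:20) {
    cu <- generate_synthetic_curves("exp1d", truth, eps,
                                    noise_sd = 0.05 * peak, seed = seed)
    pr <- fit_problem(cu, "exp1d", c("A", "B"),
                      bounds = list(A = c(1e-3, 100), B = c(1, 60)),
                      init = c(A = 1, B = 6))
    res <- fit(pr)
    if (abs(res$params[["B"]] - 12) / 12 < 0.10) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("bias of the fitted exponent under noise shrinks as n grows", {
  truth <- list(basal = exp_law(2, 12))
  bias_at <- function(n) {
    eps <- seq(0, 0.3, length.out = n)
    peak <- max(stress_1d(truth$basal, eps))
    bhat <- vapply(1:12, function(seed) {
      cu <- generate_synthetic_curves("exp1d", truth, eps,
                                      noise_sd = 0.05 * peak,
                                      seed = 100 + seed)
      pr <- fit_problem(cu, "exp1d", c("A", "B"),
                        bounds = list(A = c(1e-3, 100), B = c(1, 60)),
                        init = c(A = 1, B = 6))
      fit(pr)$params[["B"]]
    }, 0)
    abs(mean(bhat) - 12)
  }
  b <- vapply(c(10, 50, 200), bias_at, 0)
  expect_lt(b[3], b[1])
  expect_lt(b[2], b[1] * 1.5)
})

test_that("fitted default tissue laws track the generating parameters", {
  laws <- fit_tissue_laws(seed = 1)
  truth <- default_tissue_laws()
  for (nm in names(truth)) {
    expect_equal(laws[[nm]]$B, truth[[nm]]$B,
                 tolerance = 0.15, label = paste("B for", nm))
    expect_identical(laws[[nm]]$tension_only, truth[[nm]]$tension_only)
  }
  # chordae stiffer than leaflets, marginal stiffer than basal, and
  # circumferential stiffer than radial at 10% strain, as generated
  s10 <- vapply(laws, stress_1d, 0, strain = 0.1)
  expect_gt(s10[["marginal"]], s10[["basal"]])
  expect_gt(s10[["circumferential"]], s10[["radial"]])
})

test_that("law/mode mismatches are rejected", {
  g <- seq(0, 0.3, 0.1)
  shear <- shear_test(ho_params(), "FS", g)
  expect_error(fit_problem(shear, "exp1d", "A",
                           bounds = list(A = c(0, 1)), init = c(A = 0.5)),
               "needs law")
  tissue <- stress_strain_curve("radial", g, stress_1d(exp_law(1, 10), g))
  expect_error(fit_problem(tissue, "HO-shear", "a",
                           bounds = list(a = c(0, 1)), init = c(a = 0.5)),
               "not a shear mode")
})
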