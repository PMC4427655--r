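test_that("default parameter set matches the printed passive myocardium values", {
  p <- ho_params()
  expect_identical(unclass(p),
                   list(k = 1000, a = 0.33, b = 7.08, a_ff = 0.25,
                        b_ff = 5.34, a_ss = 0, b_ss = 0, a_fs = 0,
                        b_fs = 0))
  expect_error(ho_params(a = -1), "non-negative")
})

test_that("strain energy vanishes at the identity and under rigid rotation", {
  p <- ho_params()
  expect_identical(strain_energy(p, deformation_state(diag(3))), 0)
  set.seed(11)
  for (i in 1:10) {
    R <- random_rotation()
    expect_equal(strain_energy(p, deformation_state(R)), 0,
                 tolerance = 1e-10)
  }
})

test_that("strain energy equals term-by-term hand evaluation at uniaxial stretch", {
  # F = diag(lambda, lambda^-1/2, lambda^-1/2), lambda = 1.1: each
  # energy term evaluated independently from the invariants
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  I1 <- lam^2 + 2 / lam
  I4f <- lam^2
  p <- ho_params()
  iso <- p$a / (2 * p$b) * (exp(p$b * (I1 - 3)) - 1)
  fib <- p$a_ff / (2 * p$b_ff) * (exp(p$b_ff * (I4f - 1)^2) - 1)
  # J = 1 exactly, so the volumetric term is zero
  expect_equal(strain_energy(p, deformation_state(F)), iso + fib,
               tolerance = 1e-12)
  # a zero-scale term contributes exactly zero even with zero exponent
  p0 <- ho_params(a_ss = 0, b_ss = 0)
  expect_identical(strain_energy(p0, deformation_state(F)),
                   strain_energy(p, deformation_state(F)))
})

test_that("Cauchy stress is symmetric, zero at identity, and objective", {
  p <- ho_params()
  expect_equal(cauchy_stress(p, deformation_state(diag(3))),
               matrix(0, 3, 3))
  set.seed(7)
  for (i in 1:20) {
    F <- random_deformation()
    R <- random_rotation()
    s1 <- cauchy_stress(p, deformation_state(F))
    expect_equal(s1, t(s1), tolerance = 1e-9)
    s2 <- cauchy_stress(p, deformation_state(R %*% F))
    expect_equal(s2, R %*% s1 %*% t(R), tolerance = 1e-8)
  }
})

test_that("Cauchy stress matches finite differences of the energy", {
  # sigma = J^-1 dPsi/dF F^T checked against central differences of
  # strain_energy for random admissible states
  p <- ho_params()
  fd_stress <- function(F, h = 1e-6) {
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(p, deformation_state(Fp)) -
                    strain_energy(p, deformation_state(Fm))) / (2 * h)
    }
    (P %*% t(F)) / det(F)
  }
  set.seed(42)
  for (i in 1:100) {
    F <- random_deformation()
    sig <- cauchy_stress(p, deformation_state(F))
    ref <- fd_stress(F)
    ref <- (ref + t(ref)) / 2
    expect_equal(sig, ref, tolerance = 1e-4)
  }
})

test_that("validation rejects degenerate deformation states", {
  expect_error(deformation_state(diag(c(1, 1, -1))), "positive")
  expect_error(deformation_state(diag(3), f0 = c(1, 0, 0),
                                 s0 = c(1, 0, 0)), "orthonormal")
})

test_that("shear rigs: zero shear, transverse isotropy, and isotropic NS mode", {
  p <- ho_params()
  expect_identical(shear_test(p, "FS", 0)$stress, 0)
  g <- seq(0, 0.5, by = 0.05)
  # printed set is transversely isotropic about the fiber: FN and FS
  # responses are identical point for point
  expect_identical(shear_test(p, "FN", g)$stress,
                   shear_test(p, "FS", g)$stress)
  # NS shear never stretches the fiber: removing the fiber term
  # changes nothing
  p_nofib <- ho_params(a_ff = 0, b_ff = 0)
  expect_equal(shear_test(p, "NS", g)$stress,
               shear_test(p_nofib, "NS", g)$stress, tolerance = 1e-12)
  # while FS stretches the fiber, so the fiber term contributes there
  expect_gt(max(shear_test(p, "FS", g)$stress -
                  shear_test(p_nofib, "FS", g)$stress), 0.05)
  expect_error(shear_test(p, "XX", g), "unknown mode")
})

test_that("fiber term is tension-only: no stiffness under fiber shortening", {
  p <- ho_params()
  lam <- 0.9                      # I4f < 1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  p_nofib <- ho_params(a_ff = 0, b_ff = 0)
  st <- deformation_state(F)
  expect_identical(strain_energy(p, st), strain_energy(p_nofib, st))
  expect_equal(cauchy_stress(p, st), cauchy_stress(p_nofib, st),
               tolerance = 1e-12)
})

test_that("1-D exponential law: closed form, tension floor, convexity", {
  law <- exp_law(1, 10)
  expect_identical(stress_1d(law, 0), 0)
  expect_equal(stress_1d(law, 0.1), exp(1) - 1, tolerance = 1e-12)
  chord <- exp_law(60, 45, tension_only = TRUE)
  expect_identical(stress_1d(chord, -0.05), 0)
  eps <- seq(0, 0.5, length.out = 101)
  s <- stress_1d(law, eps)
  expect_true(all(diff(s) > 0))              # strictly increasing
  expect_true(all(diff(diff(s)) > 0))        # convex
  expect_error(exp_law(-1, 10), "A must")
  expect_error(exp_law(1, 0), "B must")
})

test_that("active tension: window, peak, and linearity in T_max", {
  law <- active_law(T_max = 50, t_act = 0.1, t_dur = 0.4)
  expect_identical(active_tension(law, 0.05), 0)
  expect_identical(active_tension(law, 0.6), 0)
  expect_equal(active_tension(law, 0.3, 1), 50, tolerance = 1e-12)
  half <- active_law(T_max = 25, t_act = 0.1, t_dur = 0.4)
  for (t in seq(0, 0.9, by = 0.07))
    for (lam in c(0.9, 1, 1.15))
      expect_equal(active_tension(half, t, lam),
                   active_tension(law, t, lam) / 2, tolerance = 1e-12)
  expect_true(all(active_tension(law, seq(0, 0.9, 0.01), 0.7) >= 0))
})

test_that("stress-strain curves round-trip through CSV", {
  cu <- list(shear_test(ho_params(), "FS", seq(0, 0.4, 0.1)),
             stress_strain_curve("radial", c(0, 0.1, 0.2), c(0, 2, 5)))
  path <- tempfile(fileext = ".csv")
  write_curves(cu, path)
  back <- read_curves(path)
  expect_equal(attr(back[[1]], "mode"), "FS")
  expect_equal(back[[2]]$stress, cu[[2]]$stress, tolerance = 1e-9)
  expect_error(stress_strain_curve("radial", c(0.2, 0.1), c(1, 2)),
               "increasing")
})
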