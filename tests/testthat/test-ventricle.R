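test_that("fiber stretch: closed forms and monotonicity", {
  g <- ventricle_geometry(v_wall_ml = 150, v_cav_ref_ml = 50)
  expect_equal(fiber_stretch(g, 50), 1, tolerance = 1e-12)
  expect_equal(fiber_stretch(g, 100), (150 / 100)^(1 / 3),
               tolerance = 1e-12)
  v <- seq(10, 250, length.out = 60)
  expect_true(all(diff(fiber_stretch(g, v)) > 0))
})

test_that("cavity pressure follows the log thick-wall closure", {
  g <- ventricle_geometry(v_wall_ml = 150, v_cav_ref_ml = 40)
  p <- ho_params()
  act <- active_law(T_max = 60)
  # zero total fiber stress (unloaded volume, no activation) -> P = 0
  expect_equal(cavity_pressure(g, p, act, infarct_region(0), 0.9, 40), 0,
               tolerance = 1e-12)
  # P * 3 / ln(1 + Vw/V) reproduces the total fiber stress assembled
  # from the exported passive and active laws
  for (v in c(60, 100, 140)) for (t in c(0.05, 0.2, 0.35)) {
    lam <- fiber_stretch(g, v)
    sig <- passive_fiber_stress(p, lam) + active_tension(act, t, lam)
    expect_equal(cavity_pressure(g, p, act, infarct_region(0), t, v),
                 sig / 3 * log(1 + 150 / v), tolerance = 1e-10)
  }
  # closed form: sigma_f = 30 kPa, Vw = 150, V = 100 -> P = 10 ln 2.5
  lam <- fiber_stretch(g, 100)
  sig <- passive_fiber_stress(p, lam) +
    active_tension(act, 0.2, lam)
  P <- cavity_pressure(g, p, act, infarct_region(0), 0.2, 100)
  expect_equal(P / sig, 10 * log(2.5) / 30, tolerance = 1e-10)
  # full infarct removes all active stress: pressure is purely passive
  p_pass <- cavity_pressure(g, p, active_law(T_max = 0),
                            infarct_region(0), 0.2, 100)
  # (1 - phi) scaling: at phi = 0.6, 40% of the active part remains
  p_inf <- cavity_pressure(g, p, act, infarct_region(0.6), 0.2, 100)
  p_full <- cavity_pressure(g, p, act, infarct_region(0), 0.2, 100)
  expect_equal(p_inf - p_pass, 0.4 * (p_full - p_pass),
               tolerance = 1e-10)
})

test_that("passive pressure is non-decreasing in volume above the unloaded volume", {
  g <- ventricle_geometry()
  p <- ho_params()
  act <- active_law(T_max = 0)
  v <- seq(g$v_cav_ref_ml, 200, length.out = 80)
  pv <- vapply(v, function(vi)
    cavity_pressure(g, p, act, infarct_region(0), 0.9, vi), 0)
  expect_true(all(diff(pv) >= -1e-12))
})

test_that("long-axis length: cube-root scaling and closed form", {
  g <- ventricle_geometry(aspect = 1)
  expect_equal(long_axis_length(g, 8 * 50), 2 * long_axis_length(g, 50),
               tolerance = 1e-12)
  # V = 4*pi/3 mL: the volume-equivalent sphere has radius 1 cm,
  # L = 2 cm = 20 mm
  expect_equal(long_axis_length(g, 4 * pi / 3), 20, tolerance = 1e-12)
  g2 <- ventricle_geometry(aspect = 2)
  expect_equal(long_axis_length(g2, 4 * pi / 3), 20 * 2^(2 / 3),
               tolerance = 1e-12)
  # equal end-diastolic and end-systolic volumes give zero shortening
  expect_equal(long_axis_length(g, 120) - long_axis_length(g, 120), 0)
  # sub-unity effective shape factors are admissible
  expect_silent(ventricle_geometry(aspect = 0.8))
})

test_that("ejection fraction definition", {
  expect_equal(round(100 * ejection_fraction(103, 83), 1), 19.4)
  expect_error(ejection_fraction(0, 0), "edv")
})

test_that("EF is monotone non-increasing in infarct fraction", {
  model <- fast_model(T_max = 25)
  efs <- vapply(seq(0, 0.6, by = 0.1), function(phi)
    run_cycle(model, infarct = infarct_region(phi))$EF, 0)
  expect_true(all(diff(efs) <= 1e-6))
  expect_lt(efs[7], efs[1])
})

test_that("infarct sizing terminates at the target EF and agrees with a fine scan", {
  model <- fast_model(T_max = 25)
  ef0 <- run_cycle(model)$EF
  target <- ef0 - 0.08
  inf <- size_infarct(model, target, tol = 0.0025)
  expect_lt(abs(attr(inf, "ef_achieved") - target), 0.0025)
  # exhaustive scan at step 0.01: the bisection result lies within one
  # grid cell of the scan minimizer
  grid <- seq(0, 0.6, by = 0.01)
  efs <- vapply(grid, function(phi)
    run_cycle(model, infarct = infarct_region(phi))$EF, 0)
  best <- grid[which.min(abs(efs - target))]
  expect_lte(abs(inf$phi - best), 0.01 + 1e-9)
  # a target equal to the healthy EF needs no infarct
  inf0 <- size_infarct(model, ef0, tol = 0.0025)
  expect_identical(inf0$phi, 0)
  # unreachable targets fail loudly with the achievable range
  expect_error(size_infarct(model, 0.01), "unreachable")
})

test_that("healthy calibration hits the EF and shortening targets", {
  model <- calibrate_healthy(default_model())
  cyc <- attr(model, "healthy_cycle")
  expect_true(cyc$converged)
  expect_equal(100 * cyc$EF, 55, tolerance = 0.5 / 55)
  expect_equal(cyc$shortening, 12.1, tolerance = 0.2 / 12.1)
})
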