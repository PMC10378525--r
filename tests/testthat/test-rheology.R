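test_that("apparent viscosity and shear stress follow the power law", {
  newt <- power_law_model(k = 5, n = 1)
  expect_equal(apparent_viscosity(newt, 37.2), 5)    # Newtonian: rate-independent
  expect_equal(shear_stress(newt, 2), 10)

  thin <- power_law_model(k = 10, n = 0.5)
  expect_equal(apparent_viscosity(thin, 4), 10 * 4^-0.5)  # = 5
  expect_equal(shear_stress(thin, 4), 20)

  # thermal thinning factor: exp(-b * (T - T_ref))
  warm <- power_law_model(k = 10, n = 0.5, T_ref = 25, b = 0.1)
  expect_equal(apparent_viscosity(warm, 4, temperature = 35), 5 * exp(-1))

  expect_error(apparent_viscosity(thin, 0), "positive")
  expect_error(apparent_viscosity(thin, -3), "positive")
  expect_error(power_law_model(k = -1, n = 0.5), "positive")
  expect_warning(power_law_model(k = 1, n = 1.2), "thickening")
})

test_that("stress/rate/viscosity identity holds across random valid inputs", {
  set.seed(42)
  for (i in 1:25) {
    m <- power_law_model(k = runif(1, 0.1, 50), n = runif(1, 0.2, 1))
    g <- 10^runif(1, -1, 2)
    expect_equal(shear_stress(m, g) / g, apparent_viscosity(m, g))
  }
})

test_that("viscosity decreases with shear rate iff n < 1, stress always increases", {
  g <- 10^seq(-1, 2, length.out = 40)
  thin <- power_law_model(k = 8, n = 0.4)
  expect_true(all(diff(apparent_viscosity(thin, g)) < 0))
  expect_true(all(diff(shear_stress(thin, g)) > 0))
  newt <- power_law_model(k = 8, n = 1)
  expect_true(all(diff(apparent_viscosity(newt, g)) == 0))
})

test_that("log-log OLS recovers power-law parameters", {
  g <- 10^seq(-1, 2, length.out = 20)
  truth <- power_law_model(k = 12, n = 0.4)
  sweep <- rheology_sweep(g, apparent_viscosity(truth, g), temperature = 25)
  fit <- fit_power_law(sweep)
  expect_equal(fit$k, 12, tolerance = 1e-8)
  expect_equal(fit$n, 0.4, tolerance = 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-12)

  # constant viscosity -> Newtonian
  flat <- fit_power_law(rheology_sweep(c(1, 5, 20), rep(7, 3)))
  expect_equal(flat$n, 1, tolerance = 1e-10)
  expect_equal(flat$k, 7, tolerance = 1e-10)

  expect_error(fit_power_law(data.frame(shear_rate = c(1, 2), viscosity = c(3, 2))),
               "at least 3")
})

test_that("noisy sweeps recover parameters within 5% at 2% noise", {
  cfg <- synth_rheology_config(noise_cv = 0.02, n_points = 30L, seed = 7L)
  sweep <- synth_rheogram(cfg, concentration = 9, temperature = 25)
  fit <- fit_power_law(sweep)
  k_true <- cfg$k_base  # 9 wt% at T_ref
  expect_lt(abs(fit$k - k_true) / k_true, 0.05)
  expect_lt(abs(fit$n - cfg$n) / cfg$n, 0.05)
})

test_that("viscosity mutation detector finds the gel surge and rejects flat ramps", {
  for (Tg in c(31, 26)) {
    ramp <- synth_thermal_ramp(synth_gel_config(gel_temperature = Tg))
    gp <- gel_point_from_viscosity(ramp)
    expect_equal(gp$method, "viscosity_mutation")
    expect_lt(abs(gp$temperature - Tg), 0.25)
  }
  # a linear ramp has no mutation point
  lin <- thermal_ramp(seq(0, 45, by = 0.5), seq(100, 10, length.out = 91))
  expect_error(gel_point_from_viscosity(lin), "no mutation point")
  # a surge-free smooth decay is also rejected
  smooth <- synth_thermal_ramp(synth_gel_config(surge_magnitude = 0))
  expect_error(gel_point_from_viscosity(smooth), "no mutation point")
})

test_that("loss tangent is G''/G' with the standard classification", {
  expect_equal(loss_tangent(100, 100)$tan_delta, 1)
  el <- loss_tangent(200, 50)
  expect_equal(el$tan_delta, 0.25)
  expect_equal(el$classification, "elastic/solid")
  lq <- loss_tangent(50, 200)
  expect_equal(lq$tan_delta, 4)
  expect_equal(lq$classification, "liquid")
  expect_error(loss_tangent(-1, 5), "positive")
})

test_that("modulus crossover locates the gel point by interpolation", {
  osc <- synth_oscillatory(synth_gel_config(gel_temperature = 31))
  gp <- gel_point_from_crossover(osc)
  expect_equal(gp$method, "modulus_crossover")
  expect_lt(abs(gp$temperature - 31), 0.1)

  # G' > G'' everywhere: no crossover
  solid <- oscillatory_sweep(20:30, rep(200, 11), rep(50, 11))
  expect_error(gel_point_from_crossover(solid), "no crossover")

  # symmetric two-point straddle interpolates to the midpoint
  two <- oscillatory_sweep(c(30, 32), c(110, 90), c(90, 110))
  expect_equal(gel_point_from_crossover(two)$temperature, 31)

  # multiple sign changes are ambiguous, not silently resolved
  wob <- oscillatory_sweep(c(20, 25, 30, 35), c(110, 90, 110, 90), c(90, 110, 90, 110))
  expect_error(gel_point_from_crossover(wob), "ambiguous")
})

test_that("the two gel-point methods agree on paired synthetic data", {
  cfg <- synth_gel_config(gel_temperature = 31)
  t_visc <- gel_point_from_viscosity(synth_thermal_ramp(cfg))$temperature
  t_cross <- gel_point_from_crossover(synth_oscillatory(cfg))$temperature
  expect_lt(abs(t_visc - t_cross), 0.5)
})

test_that("sweep constructors enforce their invariants", {
  expect_error(rheology_sweep(c(1, 2, 2), c(1, 1, 1)), "increasing")
  expect_error(rheology_sweep(c(1, 2, 3), c(1, -1, 1)), "positive")
  expect_error(rheology_sweep(c(1, 2, 3), c(2, 1, 0.5), stress = c(2, 2, 2)),
               "inconsistent")
  ok <- rheology_sweep(c(1, 2, 4), c(4, 2.83, 2), stress = c(4, 5.66, 8))
  expect_s3_class(ok, "rheology_sweep")
  expect_error(thermal_ramp(c(1, 2, 3, 4), c(1, 2, 3, 4)), "at least 5")
  expect_error(oscillatory_sweep(1:3, c(1, 2, 3), c(1, -2, 3)), "positive")
})
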