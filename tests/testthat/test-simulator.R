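test_that("bang-bang thermostat: stop above the band, start below, hold inside", {
  st <- thermostat_state(heater_on = TRUE)
  expect_false(thermostat_step(st, 32.5)$heater_on)   # T - 32 > 0: stop
  off <- thermostat_state(heater_on = FALSE)
  expect_true(thermostat_step(off, 29.0)$heater_on)   # T - 30 < 0: start
  expect_true(thermostat_step(st, 31.0)$heater_on)    # hysteresis: unchanged
  expect_false(thermostat_step(off, 31.0)$heater_on)
  expect_error(thermostat_state(lower_band = 33), "below")
})

test_that("a uniform field in equilibrium with its surroundings stays put", {
  # no jacket, ambient equal to the material temperature: every boundary
  # flux vanishes, so one step must leave the field unchanged
  g <- channel_geometry(jacketed_length = 0)
  cond <- process_conditions(inlet_velocity = 0.03,
                             initial_material_temperature = 30,
                             ambient_temperature = 30)
  fs <- step_thermal(NULL, dt = 0.05, geometry = g, conditions = cond,
                     material = default_material(), grid = grid_spec(13, 30))
  expect_lt(max(abs(fs$temperature - 30)), 1e-12)
})

test_that("an advected slug translates at the local axial speed", {
  # nearly uniform channel, conduction switched off: the centerline row is
  # pure upwind advection, whose first moment moves exactly u * t
  g <- channel_geometry(nozzle_diameter = 13, taper_length = 5,
                        nozzle_land_length = 3, jacketed_length = 0)
  cond <- process_conditions(inlet_velocity = 1,
                             initial_material_temperature = 20,
                             ambient_temperature = 20)
  mat <- material_properties(power_law_model(5, 0.5), k_cond = 1e-9)
  gr <- grid_spec(nr = 9, nz = 59)
  fs <- step_thermal(NULL, dt = 0.2, geometry = g, conditions = cond,
                     material = mat, grid = gr)
  z <- fs$z
  fs$temperature[1L, ] <- 20 + 5 * exp(-((z - 20) / 3)^2)
  u_center <- power_law_velocity_profile(fs$Q, 7, 0.5)$u_max
  centroid <- function(T_) sum(z * (T_ - 20)) / sum(T_ - 20)
  c0 <- centroid(fs$temperature[1L, ])
  n_steps <- 30L
  for (s in seq_len(n_steps))
    fs <- step_thermal(fs, dt = 0.2, geometry = g, conditions = cond,
                       material = mat, grid = gr)
  shift <- centroid(fs$temperature[1L, ]) - c0
  expect_equal(shift, u_center * n_steps * 0.2, tolerance = 1e-6)
})

test_that("the stability check names the admissible time step", {
  err <- tryCatch(
    step_thermal(NULL, dt = 100, geometry = default_geometry(),
                 conditions = process_conditions(0.03, 30),
                 material = default_material(), grid = grid_spec(9, 30)),
    error = function(e) conditionMessage(e))
  expect_match(err, "stability bound")
  expect_match(err, "admissible dt")
})

test_that("short transient run satisfies the field-state invariants", {
  res <- run_simulation(default_geometry(), process_conditions(0.03, 30),
                        default_material(), grid_spec(17, 59),
                        duration = 30, record_dt = 5)
  expect_true(all(diff(res$times) > 0))                    # strictly increasing
  q <- section_flow_rates(res$final)
  expect_lt((max(q) - min(q)) / mean(q), 1e-3)             # mass conservation
  expect_equal(res$final$p[length(res$final$p)], 101325)   # outlet pressure BC
  expect_true(all(res$final$viscosity > 0))
  # snapshots are captured at requested times
  res2 <- run_simulation(default_geometry(), process_conditions(0.03, 30),
                         default_material(), grid_spec(13, 30),
                         duration = 10, record_dt = 5, snapshot_times = 5)
  expect_length(res2$snapshots, 1L)
  expect_gte(res2$snapshots[[1L]]$time, 5)
})

test_that("viscosity field follows the constitutive law on the fields", {
  res <- run_simulation(default_geometry(), process_conditions(0.03, 30),
                        default_material(), grid_spec(17, 59),
                        duration = 5, record_dt = 5)
  fs <- res$final
  nr <- length(fs$zeta); nz <- length(fs$z)
  # shear thinning: wall viscosity below centerline viscosity on any section
  expect_true(all(fs$viscosity[nr, ] < fs$viscosity[1L, ]))
  # off the floor region eta = k_eff(T) * gamma^(n-1) pointwise
  m <- default_material()$rheology
  sel <- fs$shear_rate > 1e-3
  expect_equal(fs$viscosity[sel],
               (consistency_at(m, fs$temperature) * fs$shear_rate^(m$n - 1))[sel])
  # Newtonian material: viscosity varies only through temperature
  resN <- run_simulation(default_geometry(), process_conditions(0.03, 30),
                         material_properties(power_law_model(5, 1, T_ref = 25, b = 0.03)),
                         grid_spec(9, 30), duration = 5, record_dt = 5)
  fsN <- resN$final
  expect_equal(fsN$viscosity, consistency_at(power_law_model(5, 1, T_ref = 25, b = 0.03),
                                             fsN$temperature))
})

test_that("outlet temperature decreases toward equilibrium at T0 = 30", {
  res <- run_simulation(default_geometry(), process_conditions(0.03, 30),
                        default_material(), grid_spec(13, 59),
                        duration = 150, record_dt = 5)
  x <- res$outlet_mean_T
  expect_lt(x[length(x)], x[1L])
  # late-time variation is a small fraction of the initial drop
  late <- abs(diff(tail(x, 5)))
  expect_lt(max(late), 0.05 * (x[1L] - min(x)))
})
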