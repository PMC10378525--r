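#' Process (boundary and initial) conditions of an extrusion run
#'
#' Defaults are the studied operating point: piston speeds 0.03-0.09 mm/s,
#' 45 degC heating jacket, 5 degC chilled chamber, atmospheric outlet, and
#' measured initial temperatures of 24.3 degC (barrel wall) and 13.5 degC
#' (fixed block; the block is lumped into the ambient-side heat loss).
#'
#' @param inlet_velocity Piston speed v_j, mm/s, > 0.
#' @param initial_material_temperature Material temperature at the inlet and
#'   initially throughout the channel, degrees C.
#' @param jacket_setpoint Heating-sleeve temperature, degrees C.
#' @param ambient_temperature Chamber air temperature, degrees C.
#' @param outlet_pressure Absolute pressure at the nozzle outlet, Pa.
#' @param initial_barrel_wall_temperature Initial wall (thermocouple)
#'   temperature, degrees C.
#' @param initial_block_temperature Initial fixed-block temperature, degrees
#'   C (bookkeeping; conjugate block conduction is not resolved).
#' @param wall_time_constant First-order time constant of the jacketed wall
#'   toward its target (jacket setpoint when heating, ambient when not), s.
#' @return A `process_conditions` list.
#' @export
process_conditions <- function(inlet_velocity,
                               initial_material_temperature = 30,
                               jacket_setpoint = 45,
                               ambient_temperature = 5,
                               outlet_pressure = 101325,
                               initial_barrel_wall_temperature = 24.3,
                               initial_block_temperature = 13.5,
                               wall_time_constant = 30) {
  if (inlet_velocity <= 0) stop("inlet_velocity must be positive")
  temps <- c(initial_material_temperature, jacket_setpoint, ambient_temperature,
             initial_barrel_wall_temperature, initial_block_temperature)
  if (any(temps < -20 | temps > 100)) stop("temperatures must lie within -20..100 degC")
  structure(list(inlet_velocity = inlet_velocity,
                 initial_material_temperature = initial_material_temperature,
                 jacket_setpoint = jacket_setpoint,
                 ambient_temperature = ambient_temperature,
                 outlet_pressure = outlet_pressure,
                 initial_barrel_wall_temperature = initial_barrel_wall_temperature,
                 initial_block_temperature = initial_block_temperature,
                 wall_time_constant = wall_time_constant),
            class = "process_conditions")
}

#' Material properties of the printed solution
#'
#' The rheology is the power-law constitutive model; thermal properties of
#' dilute gelatin solutions are not tabulated in the sources this package
#' models, so water-like defaults are used (overridable).
#'
#' @param rheology A [power_law_model()].
#' @param density kg/m^3.
#' @param cp Specific heat, J/(kg K).
#' @param k_cond Thermal conductivity, W/(m K).
#' @return A `material_properties` list.
#' @export
material_properties <- function(rheology, density = 1000, cp = 4000, k_cond = 0.55) {
  stopifnot(inherits(rheology, "power_law_model"))
  if (density <= 0 || cp <= 0 || k_cond <= 0) stop("thermal properties must be positive")
  structure(list(rheology = rheology, density = density, cp = cp, k_cond = k_cond),
            class = "material_properties")
}

#' Bang-bang heater thermostat state
#'
#' Hysteresis control of the jacket heater on the wall thermocouple: stop
#' heating above `upper_band`, start below `lower_band`, hold otherwise.
#'
#' @param heater_on Logical, current heater state.
#' @param lower_band Start-heating threshold, degrees C.
#' @param upper_band Stop-heating threshold, degrees C.
#' @return A `thermostat_state` list.
#' @export
thermostat_state <- function(heater_on = TRUE, lower_band = 30, upper_band = 32) {
  if (lower_band >= upper_band) stop("lower_band must be below upper_band")
  structure(list(heater_on = isTRUE(heater_on), lower_band = lower_band,
                 upper_band = upper_band), class = "thermostat_state")
}

#' One thermostat decision
#'
#' @param state A [thermostat_state()].
#' @param thermocouple_T Measured wall temperature, degrees C.
#' @return The updated `thermostat_state` (hysteresis: unchanged inside the
#'   band).
#' @export
thermostat_step <- function(state, thermocouple_T) {
  if (thermocouple_T > state$upper_band) state$heater_on <- FALSE
  else if (thermocouple_T < state$lower_band) state$heater_on <- TRUE
  state
}

#' Numerical grid for the channel simulator
#'
#' @param nr Radial nodes (normalized radius, axis to wall), >= 5.
#' @param nz Axial stations inlet to outlet, >= 10. The default spacings
#'   place nodes exactly on the barrel/taper and taper/land junctions of the
#'   default geometry.
#' @param dt Fixed time step, s, or `NULL` to choose it from the advection
#'   CFL bound.
#' @param cfl_safety Fraction of the stability bound used when `dt` is
#'   chosen automatically.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(nr = 17L, nz = 59L, dt = NULL, cfl_safety = 0.8) {
  if (nr < 5L) stop("need at least 5 radial nodes")
  if (nz < 10L) stop("need at least 10 axial stations")
  if (cfl_safety <= 0 || cfl_safety > 1) stop("cfl_safety must lie in (0, 1]")
  structure(list(nr = as.integer(nr), nz = as.integer(nz), dt = dt,
                 cfl_safety = cfl_safety), class = "grid_spec")
}

# ---- internal solver machinery -------------------------------------------
#
# Quasi-1D reduction of the non-isothermal channel flow:
#  * flow: fully developed power-law profile at every axial station from the
#    global flow rate Q and local radius R(z) (lubrication theory; the
#    profile shape depends on n only, so the velocity field is steady);
#  * heat: axisymmetric advection-diffusion on the normalized radial
#    coordinate zeta = r/R(z). Lines of constant zeta approximate
#    streamlines for self-similar profiles, so advecting along them at the
#    local axial speed absorbs the taper's radial velocity.
#  * scheme: explicit first-order upwind in z (CFL-limited dt), explicit
#    central axial diffusion, implicit radial diffusion (batched Thomas
#    solve, factorization precomputed per column since geometry and dt are
#    fixed).
# Internal thermal units: mm, s, degC; conductivity W/(mm K), volumetric
# heat capacity J/(mm^3 K).

.sim_context <- function(geometry, conditions, material, grid,
                         convection = convection_config(), thermostat = thermostat_state()) {
  nr <- grid$nr; nz <- grid$nz
  z <- seq(0, geometry$total_length, length.out = nz)
  dz <- z[2L] - z[1L]
  R <- radius_profile(geometry, z)
  zeta <- seq(0, 1, length.out = nr)
  Q <- volumetric_flow(conditions$inlet_velocity, geometry$barrel_inner_diameter)
  n <- material$rheology$n

  if (Q > 0) {
    u_mean <- Q / (pi * R^2)
    u_max <- (3 * n + 1) / (n + 1) * u_mean
    U <- outer(1 - zeta^((n + 1) / n), u_max)      # nr x nz
    G <- outer(zeta^(1 / n), (3 * n + 1) / n * Q / (pi * R^3))
  } else {
    U <- matrix(0, nr, nz)
    G <- matrix(0, nr, nz)
  }

  alpha <- material$k_cond / (material$density * material$cp) * 1e6  # mm^2/s
  kc_mm <- material$k_cond * 1e-3                                    # W/(mm K)
  # exterior heat loss below the jacket: natural convection to chamber air,
  # coefficient frozen at the run's nominal film temperature
  h <- natural_convection_h(conditions$initial_material_temperature,
                            conditions$ambient_temperature, convection)
  h_over_k <- h * 1e-6 / kc_mm                                       # 1/mm

  # stability bound: axial advection CFL and explicit axial diffusion
  dt_bound <- min(if (max(U) > 0) dz / max(U) else Inf, dz^2 / (2 * alpha))
  dt <- grid$dt
  if (is.null(dt)) dt <- grid$cfl_safety * dt_bound
  else if (dt > dt_bound)
    stop(sprintf("time step %.4g s violates the stability bound; admissible dt <= %.4g s",
                 dt, dt_bound))

  jacketed <- z <= min(geometry$jacketed_length, geometry$barrel_length)

  # implicit radial operator per column: tridiagonal (A sub, B diag, C sup)
  dr <- R / (nr - 1L)
  A <- B <- C <- matrix(0, nr, nz)
  rhs_add <- matrix(0, nr, nz)   # constant additive RHS (Robin ambient term)
  i <- 2:(nr - 1L)
  for (j in seq_len(nz)) {
    s <- dt * alpha / dr[j]^2
    B[1L, j] <- 1 + 4 * s; C[1L, j] <- -4 * s
    A[i, j] <- -s * (i - 1.5) / (i - 1)
    C[i, j] <- -s * (i - 0.5) / (i - 1)
    B[i, j] <- 1 + 2 * s
    if (jacketed[j]) {            # Dirichlet wall (RHS set to wall T each step)
      A[nr, j] <- 0; B[nr, j] <- 1
    } else {                      # Robin wall: -k dT/dr = h (T - T_ambient)
      r_w <- R[j]; r_bar <- r_w - dr[j] / 4
      c1 <- 2 * (r_w - dr[j] / 2) / (r_bar * dr[j]^2)
      c2 <- 2 * h_over_k * r_w / (r_bar * dr[j])
      A[nr, j] <- -dt * alpha * c1
      B[nr, j] <- 1 + dt * alpha * (c1 + c2)
      rhs_add[nr, j] <- dt * alpha * c2 * conditions$ambient_temperature
    }
  }
  # Thomas factorization (columns are independent; batched across z)
  D <- matrix(0, nr, nz); Lf <- matrix(0, nr, nz)
  D[1L, ] <- B[1L, ]
  for (ii in 2:nr) {
    Lf[ii, ] <- A[ii, ] / D[ii - 1L, ]
    D[ii, ] <- B[ii, ] - Lf[ii, ] * C[ii - 1L, ]
  }

  # area-weighted section mean: integral of T * 2 zeta dzeta (trapezoid)
  w <- zeta; w[c(1L, nr)] <- w[c(1L, nr)] / 2
  w <- w / sum(w)

  list(geometry = geometry, conditions = conditions, material = material,
       convection = convection, thermostat = thermostat,
       nr = nr, nz = nz, z = z, dz = dz, R = R, zeta = zeta, Q = Q,
       U = U, G = G, alpha = alpha, h = h, dt = dt, dt_bound = dt_bound,
       jacketed = jacketed, C = C, D = D, Lf = Lf, rhs_add = rhs_add,
       w_section = w)
}

.sim_init_state <- function(ctx) {
  list(time = 0,
       T = matrix(ctx$conditions$initial_material_temperature, ctx$nr, ctx$nz),
       wall_T = ctx$conditions$initial_barrel_wall_temperature,
       thermostat = ctx$thermostat)
}

.sim_step <- function(ctx, state) {
  T <- state$T; nr <- ctx$nr; nz <- ctx$nz; dt <- ctx$dt
  # jacketed-wall temperature: first-order relaxation + bang-bang control
  target <- if (state$thermostat$heater_on) ctx$conditions$jacket_setpoint
            else ctx$conditions$ambient_temperature
  wall_T <- state$wall_T + dt / ctx$conditions$wall_time_constant * (target - state$wall_T)
  thermostat <- thermostat_step(state$thermostat, wall_T)

  # explicit upwind advection along constant-zeta lines + axial diffusion
  jj <- 2:nz
  Tn <- T
  Tn[, jj] <- T[, jj] - dt / ctx$dz * ctx$U[, jj] * (T[, jj] - T[, jj - 1L])
  if (ctx$alpha > 0 && nz > 2L) {
    jd <- 2:(nz - 1L)
    Tn[, jd] <- Tn[, jd] + dt * ctx$alpha / ctx$dz^2 *
      (T[, jd + 1L] - 2 * T[, jd] + T[, jd - 1L])
  }
  Tn[, 1L] <- ctx$conditions$initial_material_temperature

  # implicit radial diffusion: batched Thomas solve across columns
  rhs <- Tn + ctx$rhs_add
  rhs[nr, ctx$jacketed] <- wall_T
  y <- rhs
  for (i in 2:nr) y[i, ] <- rhs[i, ] - ctx$Lf[i, ] * y[i - 1L, ]
  x <- y
  x[nr, ] <- y[nr, ] / ctx$D[nr, ]
  for (i in (nr - 1L):1L) x[i, ] <- (y[i, ] - ctx$C[i, ] * x[i + 1L, ]) / ctx$D[i, ]
  x[, 1L] <- ctx$conditions$initial_material_temperature  # inflow Dirichlet

  list(time = state$time + dt, T = x, wall_T = wall_T, thermostat = thermostat)
}

.section_mean_T <- function(ctx, T) as.numeric(crossprod(ctx$w_section, T))

.field_state <- function(ctx, state) {
  Tsec <- .section_mean_T(ctx, state$T)
  pd <- pressure_drop(ctx$geometry, ctx$Q, ctx$material$rheology, z = ctx$z,
                      temperature = Tsec,
                      outlet_pressure = ctx$conditions$outlet_pressure)
  structure(list(time = state$time, z = ctx$z, zeta = ctx$zeta, R = ctx$R,
                 Q = ctx$Q, temperature = state$T, u = ctx$U,
                 shear_rate = ctx$G,
                 viscosity = NULL,     # filled by viscosity_field()
                 p = pd$p, delta_p = pd$delta_p,
                 section_mean_T = Tsec,
                 wall_T = state$wall_T,
                 heater_on = state$thermostat$heater_on,
                 rheology = ctx$material$rheology),
            class = "field_state")
}

#' Pointwise apparent-viscosity field
#'
#' Evaluates the constitutive law on the simulator's fields:
#' `eta = k_eff(T) * max(shear_rate, gamma_min)^(n-1)`. The floor keeps the
#' power law finite on the centerline where the shear rate vanishes.
#'
#' @param fields A `field_state` from [run_simulation()] or [step_thermal()].
#' @param material A [material_properties()] (its `rheology` is used); may
#'   be omitted if the field state carries one.
#' @param gamma_min Shear-rate floor, 1/s.
#' @return The `field_state` with its `viscosity` matrix (Pa s) filled in.
#' @export
viscosity_field <- function(fields, material = NULL, gamma_min = 1e-3) {
  model <- if (!is.null(material)) material$rheology else fields$rheology
  g <- pmax(fields$shear_rate, gamma_min)
  fields$viscosity <- consistency_at(model, fields$temperature) * g^(model$n - 1)
  fields
}

#' Section flow rates along the channel
#'
#' Numerically integrates the axial velocity over each cross-section
#' (trapezoid in the normalized radius). For an incompressible fluid every
#' station must carry the same flow rate; this is the discrete mass-
#' conservation diagnostic.
#'
#' @param fields A `field_state`.
#' @return Numeric vector, mm^3/s, one value per axial station.
#' @export
section_flow_rates <- function(fields) {
  zeta <- fields$zeta; nr <- length(zeta)
  w <- zeta; w[c(1L, nr)] <- w[c(1L, nr)] / 2
  w <- w * (zeta[2L] - zeta[1L]) * 2 * pi
  as.numeric(crossprod(w, fields$u)) * fields$R^2
}

#' Advance the thermal field by one explicit/implicit step
#'
#' One step of the channel's axisymmetric advection-diffusion update
#' (explicit upwind axial advection, implicit radial diffusion) with the
#' thermostat-driven jacketed wall and convective exterior loss. Intended
#' for scheme-level verification; [run_simulation()] runs the same update in
#' a precomputed loop.
#'
#' @param fields A `field_state` (or `NULL` to start from the initial
#'   uniform field).
#' @param dt Time step, s; must satisfy the scheme's stability bound or an
#'   error names the admissible step.
#' @param geometry,conditions,material See [run_simulation()].
#' @param grid A [grid_spec()]; when `fields` is given its grid must match.
#' @param convection A [convection_config()].
#' @param thermostat A [thermostat_state()].
#' @return The advanced `field_state`.
#' @export
step_thermal <- function(fields = NULL, dt, geometry, conditions, material,
                         grid = grid_spec(), convection = convection_config(),
                         thermostat = thermostat_state()) {
  ctx <- .sim_context(geometry, conditions, material,
                      grid_spec(grid$nr, grid$nz, dt = dt), convection, thermostat)
  state <- if (is.null(fields)) .sim_init_state(ctx)
           else list(time = fields$time, T = fields$temperature,
                     wall_T = fields$wall_T,
                     thermostat = thermostat_state(fields$heater_on,
                                                   thermostat$lower_band,
                                                   thermostat$upper_band))
  .field_state(ctx, .sim_step(ctx, state))
}

#' Run the non-isothermal extrusion-channel simulation
#'
#' Couples the quasi-steady power-law channel flow with transient
#' axisymmetric heat transfer and the bang-bang jacket thermostat, recording
#' the outlet-section mean temperature, wall (thermocouple) temperature,
#' heater state and inlet-outlet pressure difference over time. The run is
#' fully deterministic; `seed` exists so that stochastic wrappers and
#' property tests share one calling convention.
#'
#' @param geometry A [channel_geometry()].
#' @param conditions A [process_conditions()].
#' @param material A [material_properties()].
#' @param grid A [grid_spec()].
#' @param duration Simulated time, s.
#' @param record_dt Interval between recorded time-series samples, s.
#' @param snapshot_times Times (s) at which to keep full field snapshots;
#'   the final field is always kept.
#' @param convection A [convection_config()] for the exterior heat loss.
#' @param thermostat Initial [thermostat_state()].
#' @param seed Optional integer; set for reproducibility of any downstream
#'   randomness (the solver itself is deterministic).
#' @return An `ldm_simulation_result`: list with `times`, `outlet_mean_T`,
#'   `delta_p`, `wall_T`, `heater_on` (the time series), `final` (the final
#'   `field_state` with viscosity filled in), `snapshots`, `dt`, and the
#'   resolved inputs.
#' @export
run_simulation <- function(geometry, conditions, material, grid = grid_spec(),
                           duration, record_dt = 2,
                           snapshot_times = numeric(),
                           convection = convection_config(),
                           thermostat = thermostat_state(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctx <- .sim_context(geometry, conditions, material, grid, convection, thermostat)
  state <- .sim_init_state(ctx)
  n_steps <- max(1L, ceiling(duration / ctx$dt))
  stride <- max(1L, floor(record_dt / ctx$dt))
  n_rec <- floor(n_steps / stride) + 2L
  times <- numeric(n_rec); outlet_T <- numeric(n_rec)
  wall_T <- numeric(n_rec); heater <- logical(n_rec); dpv <- numeric(n_rec)
  snaps <- list()
  snap_due <- sort(snapshot_times)
  rec <- function(idx, st) {
    times[idx] <<- st$time
    outlet_T[idx] <<- sum(ctx$w_section * st$T[, ctx$nz])
    wall_T[idx] <<- st$wall_T
    heater[idx] <<- st$thermostat$heater_on
    fs <- .field_state(ctx, st)
    dpv[idx] <<- fs$delta_p
    fs
  }
  rec(1L, state)
  k <- 1L
  for (s in seq_len(n_steps)) {
    state <- .sim_step(ctx, state)
    if (length(snap_due) && state$time >= snap_due[1L]) {
      snaps[[length(snaps) + 1L]] <- viscosity_field(.field_state(ctx, state), ctx$material)
      snap_due <- snap_due[-1L]
    }
    if (s %% stride == 0L) { k <- k + 1L; rec(k, state) }
  }
  if (state$time > times[k]) { k <- k + 1L; fs <- rec(k, state) }
  else fs <- .field_state(ctx, state)
  final <- viscosity_field(fs, ctx$material)
  structure(list(times = times[1:k], outlet_mean_T = outlet_T[1:k],
                 delta_p = dpv[1:k], wall_T = wall_T[1:k],
                 heater_on = heater[1:k],
                 final = final, snapshots = snaps, dt = ctx$dt,
                 geometry = geometry, conditions = conditions,
                 material = material, grid = grid),
            class = "ldm_simulation_result")
}

#' @export
print.ldm_simulation_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("LDM extrusion simulation: %.0f s simulated (dt = %.4g s)\n",
              x$times[n], x$dt))
  cat(sprintf("  v_j = %g mm/s, T0 = %g degC, nozzle %g mm\n",
              x$conditions$inlet_velocity,
              x$conditions$initial_material_temperature,
              x$geometry$nozzle_diameter))
  cat(sprintf("  outlet mean T: %.2f -> %.2f degC; delta_p = %.3g Pa; heater duty %.0f%%\n",
              x$outlet_mean_T[1L], x$outlet_mean_T[n], x$delta_p[n],
              100 * mean(x$heater_on)))
  invisible(x)
}

#' Equilibrium outlet temperature of a run
#'
#' Mean of the outlet-section temperature over the trailing fraction of the
#' recorded series (default last 20 percent), used to compare operating
#' points after the start-up transient.
#'
#' @param result An `ldm_simulation_result`.
#' @param tail_frac Trailing fraction of samples to average.
#' @return Temperature in degrees C.
#' @export
equilibrium_outlet_T <- function(result, tail_frac = 0.2) {
  n <- length(result$outlet_mean_T)
  mean(result$outlet_mean_T[max(1L, ceiling((1 - tail_frac) * n)):n])
}
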