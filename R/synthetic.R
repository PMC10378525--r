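#' Configuration for synthetic rheometer flow sweeps
#'
#' The generator emulates the measured structure of gelatin flow sweeps:
#' shear-thinning power-law curves whose consistency grows with
#' concentration (power law in wt percent) and falls with temperature
#' (exponential), with multiplicative lognormal measurement noise.
#' Defaults reproduce the qualitative orderings of the measured sweeps
#' (3/6/9/12 wt percent at 25/30/35 degC, 0.1-100 1/s); the measured k and n
#' were never tabulated, so the absolute scale is illustrative.
#'
#' @param concentrations wt percent levels.
#' @param temperatures degC levels.
#' @param k_base Consistency at `conc_ref` wt percent and `T_ref`, Pa s^n.
#' @param k_concentration_exponent Exponent of `(conc / conc_ref)`.
#' @param conc_ref Reference concentration, wt percent.
#' @param n Rheological index.
#' @param b Thermal-thinning coefficient, 1/degC.
#' @param T_ref Reference temperature, degC.
#' @param noise_cv Coefficient of variation of the lognormal noise (0 =
#'   noiseless).
#' @param n_points Points per sweep, log-spaced over `rate_range`.
#' @param rate_range Shear-rate range, 1/s.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return A `synth_rheology_config` list.
#' @export
synth_rheology_config <- function(concentrations = c(3, 6, 9, 12),
                                  temperatures = c(25, 30, 35),
                                  k_base = 5, k_concentration_exponent = 2.2,
                                  conc_ref = 9, n = 0.5, b = 0.03, T_ref = 25,
                                  noise_cv = 0, n_points = 30L,
                                  rate_range = c(0.1, 100), seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  structure(list(concentrations = concentrations, temperatures = temperatures,
                 k_base = k_base,
                 k_concentration_exponent = k_concentration_exponent,
                 conc_ref = conc_ref, n = n, b = b, T_ref = T_ref,
                 noise_cv = noise_cv, n_points = as.integer(n_points),
                 rate_range = rate_range, seed = as.integer(seed)),
            class = "synth_rheology_config")
}

# true consistency implied by the generator at (concentration, temperature)
.synth_k <- function(config, concentration, temperature) {
  config$k_base * (concentration / config$conc_ref)^config$k_concentration_exponent *
    exp(-config$b * (temperature - config$T_ref))
}

#' Generate one synthetic flow sweep
#'
#' @param config A [synth_rheology_config()].
#' @param concentration wt percent.
#' @param temperature degC.
#' @return A [rheology_sweep()] on log-spaced shear rates with lognormal
#'   multiplicative noise of CV `noise_cv` (noise keeps viscosities
#'   positive, matching how rheometers report them).
#' @export
synth_rheogram <- function(config, concentration = 9, temperature = 25) {
  g <- exp(seq(log(config$rate_range[1L]), log(config$rate_range[2L]),
               length.out = config$n_points))
  k <- .synth_k(config, concentration, temperature)
  eta <- k * g^(config$n - 1)
  if (config$noise_cv > 0) {
    set.seed(config$seed + round(1000 * concentration + 7 * temperature))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    eta <- eta * exp(stats::rnorm(length(g), -sdlog^2 / 2, sdlog))
  }
  rheology_sweep(g, eta, temperature = temperature, concentration = concentration,
                 stress = eta * g)
}

#' Configuration for the synthetic gel transition
#'
#' @param gel_temperature Sol-gel transition temperature, degC (31 degC for
#'   the 9 wt percent solution the analyses target).
#' @param surge_magnitude Multiplicative viscosity surge below the gel point
#'   relative to the sol baseline.
#' @param transition_width Logistic transition width, degC.
#' @param eta_ref Baseline viscosity at `T_ref`, Pa s.
#' @param b Baseline thermal-thinning coefficient, 1/degC.
#' @param T_ref Baseline reference temperature, degC.
#' @param modulus_scale Crossover modulus scale for oscillatory sweeps, Pa.
#' @param seed Integer seed.
#' @return A `synth_gel_config` list.
#' @export
synth_gel_config <- function(gel_temperature = 31, surge_magnitude = 30,
                             transition_width = 0.8, eta_ref = 5, b = 0.03,
                             T_ref = 35, modulus_scale = 100, seed = 1L) {
  if (transition_width <= 0) stop("transition_width must be positive")
  if (surge_magnitude < 0) stop("surge_magnitude must be non-negative")
  structure(list(gel_temperature = gel_temperature,
                 surge_magnitude = surge_magnitude,
                 transition_width = transition_width, eta_ref = eta_ref,
                 b = b, T_ref = T_ref, modulus_scale = modulus_scale,
                 seed = as.integer(seed)), class = "synth_gel_config")
}

#' Synthetic viscosity-temperature ramp with a gel surge
#'
#' Smooth exponential sol baseline times a logistic surge centered at the
#' gel temperature:
#' `eta(T) = eta_ref exp(-b (T - T_ref)) * (1 + surge * logistic((Tg - T)/w))`.
#' With `surge_magnitude = 0` the ramp is a featureless smooth decay (the
#' mutation detector must reject it).
#'
#' @param config A [synth_gel_config()].
#' @param T_range Temperature span, degC.
#' @param dT Sample spacing, degC.
#' @return A [thermal_ramp()].
#' @export
synth_thermal_ramp <- function(config, T_range = c(0, 45), dT = 0.1) {
  T_ <- seq(T_range[1L], T_range[2L], by = dT)
  base <- config$eta_ref * exp(-config$b * (T_ - config$T_ref))
  surge <- 1 + config$surge_magnitude *
    stats::plogis((config$gel_temperature - T_) / config$transition_width)
  thermal_ramp(T_, base * surge)
}

#' Synthetic oscillatory temperature sweep crossing at the gel point
#'
#' Both moduli decay exponentially with temperature, the storage modulus
#' faster, so they cross exactly once at the gel temperature where
#' `tan delta = 1`; above it the sweep is liquid-like (`tan delta > 1`),
#' below it solid-like, and `tan delta` is monotone in temperature.
#'
#' @param config A [synth_gel_config()].
#' @param T_range Temperature span, degC.
#' @param dT Sample spacing, degC.
#' @param decay_storage,decay_loss Exponential decay rates, 1/degC
#'   (`decay_storage > decay_loss`).
#' @return An [oscillatory_sweep()].
#' @export
synth_oscillatory <- function(config, T_range = c(20, 40), dT = 0.25,
                              decay_storage = 0.35, decay_loss = 0.1) {
  if (decay_storage <= decay_loss) stop("storage modulus must decay faster than loss modulus")
  T_ <- seq(T_range[1L], T_range[2L], by = dT)
  dTg <- T_ - config$gel_temperature
  oscillatory_sweep(T_,
                    G_storage = config$modulus_scale * exp(-decay_storage * dTg),
                    G_loss = config$modulus_scale * exp(-decay_loss * dTg))
}

#' Synthetic line-width measurements
#'
#' Widths on a true affine law of inlet velocity plus additive Gaussian
#' noise (the standard model for a length measured off micrographs).
#'
#' @param true_law A [linear_law()].
#' @param inlet_velocities mm/s.
#' @param noise_sd Gaussian noise SD, mm (0 = exact).
#' @param seed Integer seed.
#' @return A [width_measurements()].
#' @export
synth_line_widths <- function(true_law, inlet_velocities, noise_sd = 0.05, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  w <- eval_law(true_law, inlet_velocities)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    w <- w + stats::rnorm(length(w), 0, noise_sd)
  }
  width_measurements(inlet_velocities, w)
}

#' Published inputs of the line-width study
#'
#' The printed constants of the deposition experiment, exposed as one
#' bundle: channel geometry defaults, the four inlet velocities with their
#' measured widths, the print speed, the layer thickness (both the printed
#' 0.3 mm and the 0.5 mm value that actually reproduces every printed
#' number, labeled), and the printed regression laws.
#'
#' @return A list with `geometry`, `measurements`, `v_c`, `h`,
#'   `h_as_printed`, `actual_law_printed`, `theoretical_law_printed`,
#'   `error_law_printed`.
#' @export
fixture_paper_inputs <- function() {
  list(
    geometry = channel_geometry(),
    measurements = width_measurements(
      inlet_velocity = c(0.0156, 0.0313, 0.0469, 0.0625),
      width = c(1.660, 2.280, 2.830, 3.320)),
    v_c = 5,
    h = 0.5,            # reproduces all printed widths and laws
    h_as_printed = 0.3, # value stated in the source text; inconsistent with its own numbers
    actual_law_printed = linear_law(1.1415, 35.3344),
    theoretical_law_printed = linear_law(0.1075, 61.529),
    error_law_printed = linear_law(1.0345, -26.195)
  )
}
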