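#' Power-law (pseudoplastic) constitutive model
#'
#' The apparent viscosity of a shear-thinning fluid follows
#' \eqn{\eta_a = \tau/\dot\gamma = k \dot\gamma^{n-1}}, where `k` is the
#' consistency coefficient (Pa s^n) and `n` the rheological index. Gelatin
#' solutions above the gel point thin further with temperature; an optional
#' exponential factor \eqn{k_{eff} = k e^{-b (T - T_{ref})}} models that
#' thermal thinning.
#'
#' @param k Consistency coefficient, Pa s^n. Must be positive.
#' @param n Rheological index, dimensionless. Shear thinning when `n < 1`;
#'   values above 1 (shear thickening) are accepted with a warning since the
#'   material this package targets is pseudoplastic.
#' @param T_ref Reference temperature for the thermal factor, degrees C.
#' @param b Exponential thermal-thinning coefficient, 1/degC. Default 0
#'   (temperature-independent).
#' @return An object of class `power_law_model`.
#' @examples
#' m <- power_law_model(k = 10, n = 0.5)
#' apparent_viscosity(m, shear_rate = 4) # 10 * 4^-0.5 = 5 Pa s
#' @export
power_law_model <- function(k, n, T_ref = 25, b = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(n), length(n) == 1L)
  if (!is.finite(k) || k <= 0) stop("consistency coefficient 'k' must be positive")
  if (!is.finite(n) || n <= 0) stop("rheological index 'n' must be positive")
  if (n > 1) warning("n > 1: shear-thickening model; gelatin solutions are expected pseudoplastic (n <= 1)")
  structure(list(k = k, n = n, T_ref = T_ref, b = b), class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("Power-law fluid: k = %.6g Pa.s^n, n = %.6g", x$k, x$n))
  if (x$b != 0) cat(sprintf(", b = %.4g 1/degC (T_ref = %g degC)", x$b, x$T_ref))
  cat("\n")
  invisible(x)
}

#' Effective consistency coefficient at a temperature
#'
#' @param model A [power_law_model()].
#' @param temperature Temperature in degrees C, or `NULL` to use `k` as is.
#' @return k_eff = k * exp(-b * (T - T_ref)), Pa s^n.
#' @export
consistency_at <- function(model, temperature = NULL) {
  if (is.null(temperature)) return(model$k)
  model$k * exp(-model$b * (temperature - model$T_ref))
}

#' Apparent viscosity of a power-law fluid
#'
#' @inheritParams consistency_at
#' @param shear_rate Shear rate, 1/s; strictly positive (the power law is
#'   singular at zero shear for `n < 1`).
#' @return Apparent viscosity in Pa s: `k_eff * shear_rate^(n - 1)`.
#' @export
apparent_viscosity <- function(model, shear_rate, temperature = NULL) {
  stopifnot(inherits(model, "power_law_model"))
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0))
    stop("shear_rate must be strictly positive")
  consistency_at(model, temperature) * shear_rate^(model$n - 1)
}

#' Shear stress of a power-law fluid
#'
#' @inheritParams apparent_viscosity
#' @return Shear stress in Pa: `tau = k_eff * shear_rate^n`, identically
#'   `apparent_viscosity(model, shear_rate) * shear_rate`.
#' @export
shear_stress <- function(model, shear_rate, temperature = NULL) {
  apparent_viscosity(model, shear_rate, temperature) * shear_rate
}

#' Rheometer flow sweep (viscosity vs shear rate)
#'
#' @param shear_rate Shear rates in 1/s, strictly increasing, at least 3.
#' @param viscosity Apparent viscosities in Pa s, positive.
#' @param temperature Sweep temperature, degrees C.
#' @param concentration Gelatin concentration, wt percent.
#' @param stress Optional shear stress in Pa; when given it must equal
#'   `viscosity * shear_rate` (consistency of the rheometer export).
#' @return A `rheology_sweep`: a data.frame of points with attributes.
#' @export
rheology_sweep <- function(shear_rate, viscosity, temperature = NA_real_,
                           concentration = NA_real_, stress = NULL) {
  if (length(shear_rate) < 3L) stop("a rheology sweep needs at least 3 points")
  if (length(viscosity) != length(shear_rate)) stop("shear_rate and viscosity lengths differ")
  if (any(shear_rate <= 0) || any(viscosity <= 0)) stop("shear rates and viscosities must be positive")
  if (any(diff(shear_rate) <= 0)) stop("shear rates must be strictly increasing")
  if (!is.null(stress)) {
    rel <- abs(stress - viscosity * shear_rate) / (viscosity * shear_rate)
    if (any(rel > 1e-9)) stop("stress inconsistent with viscosity * shear_rate")
  }
  df <- data.frame(shear_rate = shear_rate, viscosity = viscosity)
  if (!is.null(stress)) df$stress <- stress
  structure(df, temperature = temperature, concentration = concentration,
            class = c("rheology_sweep", "data.frame"))
}

#' Fit the power-law model to a flow sweep
#'
#' Ordinary least squares of `log(viscosity)` on `log(shear_rate)`:
#' the slope estimates `n - 1` and the intercept `log(k)`. The log-linear
#' form is exact for power-law data, closed-form, and reproducible; it is the
#' standard way rheometer software reports (k, n).
#'
#' @param sweep A [rheology_sweep()] (or data.frame with `shear_rate`,
#'   `viscosity` columns).
#' @return A [power_law_model()] with extra fields `fit` (the `lm` object),
#'   `r_squared`, and `sigma_log` (residual SD on the log scale).
#' @export
fit_power_law <- function(sweep) {
  if (!all(c("shear_rate", "viscosity") %in% names(sweep)))
    stop("sweep must have 'shear_rate' and 'viscosity' columns")
  g <- sweep$shear_rate; eta <- sweep$viscosity
  if (length(g) < 3L) stop("need at least 3 points to fit a power law")
  if (any(g <= 0) || any(eta <= 0)) stop("power-law fit requires positive data")
  fit <- stats::lm(log(eta) ~ log(g))
  co <- stats::coef(fit)
  m <- power_law_model(k = exp(unname(co[1L])), n = unname(co[2L]) + 1)
  tref <- attr(sweep, "temperature")
  if (!is.null(tref) && !is.na(tref)) m$T_ref <- tref
  m$fit <- fit
  # summary.lm warns on exact (noiseless) data; that case is legitimate here
  sm <- suppressWarnings(summary(fit))
  m$r_squared <- sm$r.squared
  m$sigma_log <- sm$sigma
  m
}

#' Viscosity-temperature ramp
#'
#' @param temperature Temperatures in degrees C, strictly ascending, >= 5.
#' @param viscosity Apparent viscosities in Pa s.
#' @return A `thermal_ramp` data.frame.
#' @export
thermal_ramp <- function(temperature, viscosity) {
  if (length(temperature) != length(viscosity)) stop("temperature and viscosity lengths differ")
  if (length(temperature) < 5L) stop("a thermal ramp needs at least 5 points")
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly ascending")
  structure(data.frame(temperature = temperature, viscosity = viscosity),
            class = c("thermal_ramp", "data.frame"))
}

#' Oscillatory temperature sweep (G', G'')
#'
#' @param temperature Temperatures in degrees C.
#' @param G_storage Storage modulus G' in Pa, positive.
#' @param G_loss Loss modulus G'' in Pa, positive.
#' @return An `oscillatory_sweep` data.frame.
#' @export
oscillatory_sweep <- function(temperature, G_storage, G_loss) {
  n <- length(temperature)
  if (length(G_storage) != n || length(G_loss) != n) stop("column lengths differ")
  if (any(G_storage <= 0) || any(G_loss <= 0)) stop("moduli must be positive")
  structure(data.frame(temperature = temperature, G_storage = G_storage, G_loss = G_loss),
            class = c("oscillatory_sweep", "data.frame"))
}

gel_point_estimate <- function(temperature, method) {
  structure(list(temperature = temperature, method = method), class = "gel_point_estimate")
}

#' @export
print.gel_point_estimate <- function(x, ...) {
  cat(sprintf("Gel point: %.2f degC (%s)\n", x$temperature, x$method))
  invisible(x)
}

#' Gel point from the viscosity mutation of a thermal ramp
#'
#' A sol-gel transition shows as an abrupt surge of viscosity on cooling
#' through the gel point. The detector smooths the ramp with a centered
#' moving average, takes central differences, and returns the temperature of
#' maximum absolute slope. A ramp with no distinct surge (max slope not
#' clearly above the typical slope) is rejected rather than silently
#' returning a meaningless extremum.
#'
#' @param ramp A [thermal_ramp()].
#' @param window Moving-average window (odd integer), default 3.
#' @param distinctness Minimum ratio of the maximum absolute derivative to
#'   the median absolute derivative for the mutation to count, default 3.
#' @return A `gel_point_estimate` with `method = "viscosity_mutation"`.
#' @export
gel_point_from_viscosity <- function(ramp, window = 3L, distinctness = 3) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  T_ <- ramp$temperature; eta <- ramp$viscosity
  if (window > 1L) {
    kern <- rep(1 / window, window)
    sm <- stats::filter(eta, kern, sides = 2)
    # keep raw values at the ends where the kernel does not fit
    eta <- ifelse(is.na(sm), eta, as.numeric(sm))
  }
  m <- length(T_)
  dEta <- (eta[3:m] - eta[1:(m - 2)]) / (T_[3:m] - T_[1:(m - 2)])
  Tc <- T_[2:(m - 1)]
  slope <- abs(dEta)
  med <- stats::median(slope)
  if (med <= 0 || max(slope) / med < distinctness)
    stop("no mutation point: viscosity derivative has no distinct maximum")
  gel_point_estimate(Tc[which.max(slope)], "viscosity_mutation")
}

#' Loss tangent and viscoelastic classification
#'
#' The loss tangent is the ratio of loss to storage modulus,
#' \eqn{\tan\delta = G''/G'}: below 1 the elastic (solid-like) response
#' dominates, above 1 the viscous (liquid-like) response. Note that some of
#' the applied literature prints the ratio the other way around while still
#' classifying "tan delta < 1" as elastic; only G''/G' is consistent with
#' that classification, so G''/G' is what this function computes.
#'
#' @param G_storage Storage modulus G' in Pa, positive.
#' @param G_loss Loss modulus G'' in Pa, positive.
#' @return A list with `tan_delta` and `classification` (one of
#'   `"elastic/solid"`, `"crossover"`, `"liquid"`), vectorized over inputs.
#' @export
loss_tangent <- function(G_storage, G_loss) {
  if (any(G_storage <= 0) || any(G_loss <= 0)) stop("moduli must be positive")
  td <- G_loss / G_storage
  cls <- ifelse(td < 1, "elastic/solid", ifelse(td > 1, "liquid", "crossover"))
  list(tan_delta = td, classification = cls)
}

#' Gel point from the G' = G'' crossover
#'
#' Finds the single temperature where the storage and loss moduli cross
#' (equivalently where tan delta crosses 1) by linear interpolation of
#' `G' - G''` between the two bracketing sample points.
#'
#' @param osc An [oscillatory_sweep()].
#' @return A `gel_point_estimate` with `method = "modulus_crossover"`.
#' @export
gel_point_from_crossover <- function(osc) {
  T_ <- osc$temperature; d <- osc$G_storage - osc$G_loss
  s <- sign(d)
  # treat exact zeros as crossings at the sample point
  hit <- which(s == 0)
  flips <- which(s[-1] * s[-length(s)] < 0)
  n_cross <- length(hit) + length(flips)
  if (n_cross == 0L) stop("no crossover: G' - G'' does not change sign over the sweep")
  if (n_cross > 1L) {
    at <- sort(c(T_[hit], (T_[flips] + T_[flips + 1L]) / 2))
    stop(sprintf("ambiguous crossover: %d sign changes near T = %s degC",
                 n_cross, paste(signif(at, 4), collapse = ", ")))
  }
  if (length(hit) == 1L) return(gel_point_estimate(T_[hit], "modulus_crossover"))
  i <- flips
  Tg <- T_[i] + (T_[i + 1L] - T_[i]) * d[i] / (d[i] - d[i + 1L])
  gel_point_estimate(Tg, "modulus_crossover")
}
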