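#' Thermophysical properties of a convecting fluid
#'
#' @param beta Volume-expansion coefficient, 1/K (ideal gas: 1/T_film).
#' @param rho Density, kg/m^3.
#' @param mu Dynamic viscosity, Pa s.
#' @param cp Specific heat capacity, J/(kg K).
#' @param k_cond Thermal conductivity, W/(m K).
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(beta, rho, mu, cp, k_cond) {
  v <- c(beta = beta, rho = rho, mu = mu, cp = cp, k_cond = k_cond)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all fluid properties must be strictly positive")
  structure(as.list(v), class = "fluid_properties")
}

# Dry air at atmospheric pressure, 250-350 K (standard heat-transfer tables);
# beta from the ideal-gas law 1/T.
.air_table <- data.frame(
  T_K  = c(250, 275, 300, 325, 350),
  rho  = c(1.3947, 1.2690, 1.1614, 1.0719, 0.9950),
  cp   = c(1006, 1006.5, 1007, 1008, 1009),
  mu   = c(159.6e-7, 172.5e-7, 184.6e-7, 196.6e-7, 208.2e-7),
  k    = c(22.3e-3, 24.3e-3, 26.3e-3, 28.2e-3, 30.0e-3)
)

#' Dry-air properties at a film temperature
#'
#' Linear interpolation in a built-in table of dry air at 1 atm over
#' 250-350 K; the volume-expansion coefficient uses the ideal-gas
#' `beta = 1/T_film`.
#'
#' @param T_film_C Film temperature in degrees C (average of surface and
#'   ambient); must lie within -23 to 77 C.
#' @return A [fluid_properties()] object.
#' @export
air_properties <- function(T_film_C) {
  TK <- T_film_C + 273.15
  if (TK < 250 || TK > 350) stop("air property table covers 250-350 K only")
  ip <- function(col) stats::approx(.air_table$T_K, .air_table[[col]], xout = TK)$y
  fluid_properties(beta = 1 / TK, rho = ip("rho"), mu = ip("mu"),
                   cp = ip("cp"), k_cond = ip("k"))
}

#' Natural-convection correlation configuration
#'
#' Defaults `c = 0.59`, `m = 0.25` are the laminar vertical-surface values
#' used for the vertically mounted material barrel.
#'
#' @param c Correlation constant, dimensionless, > 0.
#' @param m Correlation exponent, dimensionless, in (0, 1).
#' @param L Characteristic length, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return A `convection_config` list.
#' @export
convection_config <- function(c = 0.59, m = 0.25, L = 0.045, g = 9.81) {
  if (c <= 0) stop("correlation constant c must be positive")
  if (m <= 0 || m >= 1) stop("correlation exponent m must lie in (0, 1)")
  if (L <= 0) stop("characteristic length L must be positive")
  structure(list(c = c, m = m, L = L, g = g), class = "convection_config")
}

#' Grashof number
#'
#' Ratio of buoyancy to viscous forces driving natural convection:
#' \eqn{Gr = \beta g \Delta T \rho^2 L^3 / \mu^2}.
#'
#' @param props A [fluid_properties()] object.
#' @param delta_T Surface-to-ambient temperature difference, K (>= 0).
#' @param L Characteristic length, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return Dimensionless Grashof number.
#' @export
grashof <- function(props, delta_T, L, g = 9.81) {
  if (L <= 0) stop("characteristic length L must be positive")
  if (delta_T < 0) stop("delta_T must be non-negative")
  props$beta * g * delta_T * props$rho^2 * L^3 / props$mu^2
}

#' Prandtl number
#'
#' \eqn{Pr = c_p \mu / k}: the ratio of momentum to thermal diffusivity.
#'
#' @param props A [fluid_properties()] object.
#' @return Dimensionless Prandtl number.
#' @export
prandtl <- function(props) props$cp * props$mu / props$k_cond

#' Nusselt number from the natural-convection correlation
#'
#' \eqn{Nu = c (Gr \cdot Pr)^m}.
#'
#' @param Gr Grashof number, >= 0.
#' @param Pr Prandtl number, > 0.
#' @param config A [convection_config()].
#' @return Dimensionless Nusselt number.
#' @export
nusselt <- function(Gr, Pr, config = convection_config()) {
  if (Gr < 0) stop("Grashof number must be non-negative")
  if (Pr <= 0) stop("Prandtl number must be positive")
  config$c * (Gr * Pr)^config$m
}

#' Convective heat-transfer coefficient from the Nusselt number
#'
#' `h_c = Nu * k / L` (the defining relation of the Nusselt number).
#'
#' @param Nu Nusselt number.
#' @param k_cond Thermal conductivity of the convecting fluid, W/(m K).
#' @param L Characteristic length, m.
#' @return h_c in W/(m^2 K).
#' @export
convective_coefficient <- function(Nu, k_cond, L) {
  if (L <= 0) stop("characteristic length L must be positive")
  Nu * k_cond / L
}

#' Natural-convection coefficient for a surface in ambient air
#'
#' Convenience chain: air properties at the film temperature, Grashof,
#' Prandtl, Nusselt, then `h_c = Nu k / L`.
#'
#' @param surface_T_C Surface temperature, degrees C.
#' @param ambient_T_C Ambient air temperature, degrees C.
#' @param config A [convection_config()].
#' @return h_c in W/(m^2 K); 0 when the temperatures are equal.
#' @export
natural_convection_h <- function(surface_T_C, ambient_T_C, config = convection_config()) {
  props <- air_properties((surface_T_C + ambient_T_C) / 2)
  Gr <- grashof(props, abs(surface_T_C - ambient_T_C), config$L, config$g)
  convective_coefficient(nusselt(Gr, prandtl(props), config), props$k_cond, config$L)
}
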