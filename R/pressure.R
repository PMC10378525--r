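#' Axial pressure gradient of power-law tube flow
#'
#' From the wall force balance of fully developed laminar flow,
#' \eqn{-dp/dz = 2\tau_w/R} with
#' \eqn{\tau_w = k_{eff}(T) \dot\gamma_w^n} and the Rabinowitsch-Mooney wall
#' shear rate. Returned as a positive magnitude (pressure falls toward the
#' outlet). Reduces exactly to Hagen-Poiseuille for n = 1.
#'
#' @param Q Volumetric flow rate, mm^3/s (0 allowed: no flow, no gradient).
#' @param R Local channel radius, mm.
#' @param model A [power_law_model()].
#' @param temperature Local temperature, degrees C (optional; enters through
#'   the thermal-thinning factor of the model).
#' @return |dp/dz| in Pa/mm.
#' @export
pressure_gradient <- function(Q, R, model, temperature = NULL) {
  if (Q < 0 || R <= 0) stop("Q must be >= 0 and R > 0")
  if (Q == 0) return(0)
  gw <- wall_shear_rate(Q, R, model$n)
  tau_w <- consistency_at(model, temperature) * gw^model$n
  2 * tau_w / R
}

# Exact integral of R(z)^-(m) over one axial interval where R varies
# linearly from Ra to Rb over length L (cone segment); closed form avoids
# the severe quadrature error of trapezoid on the taper's R^-4-like kink.
.segment_radius_integral <- function(Ra, Rb, L, m) {
  if (L <= 0) return(0)
  if (abs(Rb - Ra) < 1e-12 * max(Ra, Rb)) return(L * Ra^(-m))
  L / (Rb - Ra) * (Rb^(1 - m) - Ra^(1 - m)) / (1 - m)
}

#' Pressure distribution and inlet-outlet pressure drop along the channel
#'
#' Integrates the lubrication-theory pressure gradient
#' \eqn{-dp/dz = 2 k_{eff}(T(z)) \dot\gamma_w(z)^n / R(z)} along the channel.
#' Within each axial interval the consistency is evaluated at the interval
#' midpoint temperature and the purely geometric factor
#' \eqn{\int R^{-(3n+1)} dz} is integrated in closed form (exact for the
#' piecewise-linear radius profile), so the isothermal Newtonian case
#' reproduces the piecewise Hagen-Poiseuille sum to machine precision for
#' any grid that resolves the section breaks.
#'
#' @param geometry A [channel_geometry()].
#' @param Q Volumetric flow rate, mm^3/s.
#' @param model A [power_law_model()].
#' @param z Axial stations, mm, ascending from 0 to `total_length`; at least
#'   10 stations.
#' @param temperature Either a single temperature (degrees C), a vector of
#'   section-mean temperatures at `z`, or `NULL` for the model's reference.
#' @param outlet_pressure Absolute pressure at the outlet, Pa (1 atm default).
#' @return List with `z`, `p` (absolute pressure, Pa, `p[outlet] =
#'   outlet_pressure`), and `delta_p` (inlet minus outlet, Pa).
#' @export
pressure_drop <- function(geometry, Q, model, z = NULL,
                          temperature = NULL, outlet_pressure = 101325) {
  if (is.null(z)) z <- channel_axial_grid(geometry, dz = 0.5)
  if (length(z) < 10L) stop("axial grid too coarse: need at least 10 stations")
  if (any(diff(z) <= 0) || z[1L] != 0 || abs(z[length(z)] - geometry$total_length) > 1e-9)
    stop("z must ascend from 0 to total_length")
  nz <- length(z)
  Tv <- if (is.null(temperature)) rep(model$T_ref, nz)
        else if (length(temperature) == 1L) rep(temperature, nz)
        else temperature
  if (length(Tv) != nz) stop("temperature must be scalar or one value per station")
  n <- model$n
  m <- 3 * n + 1
  R <- radius_profile(geometry, z)
  Cn <- 2 * ((3 * n + 1) / (4 * n) * 4 * Q / pi)^n
  dp_seg <- numeric(nz - 1L)
  for (i in seq_len(nz - 1L)) {
    k_eff <- consistency_at(model, (Tv[i] + Tv[i + 1L]) / 2)
    dp_seg[i] <- k_eff * Cn * .segment_radius_integral(R[i], R[i + 1L], z[i + 1L] - z[i], m)
  }
  # accumulate upstream from the outlet boundary condition
  p <- outlet_pressure + rev(cumsum(rev(c(dp_seg, 0))))
  list(z = z, p = p, delta_p = p[1L] - outlet_pressure)
}

#' Axial grid resolving the channel's section breaks
#'
#' Builds an ascending axial grid with target spacing `dz` in the barrel and
#' a finer spacing in the taper and nozzle land (where the radius, velocity
#' and pressure gradient vary fastest), always placing nodes exactly on the
#' barrel/taper and taper/land junctions.
#'
#' @param geometry A [channel_geometry()].
#' @param dz Target barrel spacing, mm.
#' @param refine Refinement factor for taper and land, default 4.
#' @return Numeric vector of z stations, mm.
#' @export
channel_axial_grid <- function(geometry, dz = 0.5, refine = 4) {
  z1 <- geometry$barrel_length
  z2 <- z1 + geometry$taper_length
  zt <- geometry$total_length
  seg <- function(a, b, h) seq(a, b, length.out = max(2L, ceiling((b - a) / h) + 1L))
  z <- c(seg(0, z1, dz), seg(z1, z2, dz / refine), seg(z2, zt, dz / refine))
  sort(unique(z))
}
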