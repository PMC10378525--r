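#' Barrel-taper-nozzle channel geometry
#'
#' The extrusion channel of the LDM print head: a cylindrical material
#' barrel, a conical taper, and a short cylindrical nozzle land. Axial
#' coordinate z runs from the piston inlet (z = 0) to the nozzle outlet
#' (z = total_length). Defaults are the printed dimensions of the studied
#' device (14 mm bore, 58 mm inlet-to-outlet, 1 mm outlet); taper and land
#' lengths are not printed and default to 5 mm and 3 mm.
#'
#' @param barrel_inner_diameter Barrel bore d1, mm.
#' @param barrel_outer_diameter Barrel outer diameter, mm (bookkeeping only).
#' @param total_length Inlet-to-outlet length, mm.
#' @param taper_length Length of the conical contraction, mm.
#' @param nozzle_land_length Length of the cylindrical nozzle land, mm.
#' @param nozzle_diameter Outlet diameter d, mm.
#' @param jacketed_length Axial extent of the heating jacket from the inlet,
#'   mm (the silicone sleeve is 45 mm tall).
#' @return A `channel_geometry` list.
#' @export
channel_geometry <- function(barrel_inner_diameter = 14,
                             barrel_outer_diameter = 17,
                             total_length = 58,
                             taper_length = 5,
                             nozzle_land_length = 3,
                             nozzle_diameter = 1,
                             jacketed_length = 45) {
  if (nozzle_diameter <= 0 || nozzle_diameter >= barrel_inner_diameter)
    stop("nozzle_diameter must lie in (0, barrel_inner_diameter)")
  if (taper_length + nozzle_land_length >= total_length)
    stop("taper_length + nozzle_land_length must be smaller than total_length")
  if (jacketed_length < 0 || jacketed_length > total_length)
    stop("jacketed_length must lie within the channel")
  structure(list(
    barrel_inner_diameter = barrel_inner_diameter,
    barrel_outer_diameter = barrel_outer_diameter,
    total_length = total_length,
    taper_length = taper_length,
    nozzle_land_length = nozzle_land_length,
    nozzle_diameter = nozzle_diameter,
    jacketed_length = jacketed_length,
    barrel_length = total_length - taper_length - nozzle_land_length
  ), class = "channel_geometry")
}

#' Channel radius at an axial position
#'
#' Piecewise profile: constant barrel radius, linear cone over the taper,
#' constant nozzle radius over the land.
#'
#' @param geometry A [channel_geometry()].
#' @param z Axial positions, mm, within `[0, total_length]`.
#' @return Inner radius R(z) in mm (vectorized).
#' @export
radius_profile <- function(geometry, z) {
  if (any(z < 0 | z > geometry$total_length)) stop("z outside the channel")
  Rb <- geometry$barrel_inner_diameter / 2
  Rn <- geometry$nozzle_diameter / 2
  z1 <- geometry$barrel_length
  z2 <- z1 + geometry$taper_length
  r <- ifelse(z <= z1, Rb,
       ifelse(z >= z2, Rn, Rb + (Rn - Rb) * (z - z1) / geometry$taper_length))
  as.numeric(r)
}

#' Volumetric flow rate from the piston speed
#'
#' The piston advances at the inlet velocity over the full barrel bore,
#' so `Q = v_j * pi * d1^2 / 4`.
#'
#' @param inlet_velocity Piston (inlet) velocity v_j, mm/s.
#' @param barrel_inner_diameter Barrel bore d1, mm.
#' @return Q in mm^3/s.
#' @export
volumetric_flow <- function(inlet_velocity, barrel_inner_diameter) {
  if (inlet_velocity < 0 || barrel_inner_diameter <= 0) stop("inputs must be positive")
  inlet_velocity * pi * barrel_inner_diameter^2 / 4
}

#' Continuity-implied mean velocity at the nozzle outlet
#'
#' For an incompressible fluid the section-average speed at the outlet is
#' `Q / (pi d^2 / 4)`, i.e. `v_j * (d1/d)^2`.
#'
#' @param Q Volumetric flow rate, mm^3/s.
#' @param nozzle_diameter Outlet diameter d, mm.
#' @return Section-average outlet speed, mm/s.
#' @export
mean_outlet_velocity <- function(Q, nozzle_diameter) {
  if (Q < 0 || nozzle_diameter <= 0) stop("inputs must be positive")
  Q / (pi * nozzle_diameter^2 / 4)
}

#' Fully developed power-law velocity profile in a tube
#'
#' Laminar, fully developed axial flow of a power-law fluid in a circular
#' section of radius R:
#' \eqn{u(r) = u_{max} [1 - (r/R)^{(n+1)/n}]} with
#' \eqn{u_{max} = \frac{3n+1}{n+1} \frac{Q}{\pi R^2}}.
#' The Newtonian limit n = 1 is the parabolic Poiseuille profile.
#'
#' @param Q Volumetric flow rate, mm^3/s, > 0.
#' @param R Tube radius, mm, > 0.
#' @param n Rheological index, > 0.
#' @param r Radial positions, mm, in `[0, R]`; default 50 evenly spaced.
#' @return List with `r`, `u` (mm/s), `u_max`, `u_mean = Q/(pi R^2)`.
#' @export
power_law_velocity_profile <- function(Q, R, n, r = seq(0, R, length.out = 50L)) {
  if (Q <= 0 || R <= 0) stop("Q and R must be positive")
  if (n <= 0) stop("rheological index n must be positive")
  if (any(r < 0 | r > R)) stop("r must lie in [0, R]")
  u_mean <- Q / (pi * R^2)
  u_max <- (3 * n + 1) / (n + 1) * u_mean
  u <- u_max * (1 - (r / R)^((n + 1) / n))
  list(r = r, u = u, u_max = u_max, u_mean = u_mean)
}

#' Wall shear rate of power-law tube flow (Rabinowitsch-Mooney)
#'
#' \eqn{\dot\gamma_w = \frac{3n+1}{4n} \cdot \frac{4Q}{\pi R^3}}: the
#' Newtonian wall shear rate corrected by the Rabinowitsch-Mooney factor.
#'
#' @inheritParams power_law_velocity_profile
#' @return Wall shear rate, 1/s.
#' @export
wall_shear_rate <- function(Q, R, n) {
  if (Q <= 0 || R <= 0 || n <= 0) stop("inputs must be positive")
  (3 * n + 1) / (4 * n) * 4 * Q / (pi * R^3)
}

#' Local shear-rate magnitude of the power-law profile
#'
#' |du/dr| for the fully developed profile; zero on the axis, maximal at the
#' wall where it equals [wall_shear_rate()].
#'
#' @inheritParams power_law_velocity_profile
#' @param r Radial positions, mm, in `[0, R]`.
#' @return Shear rate in 1/s (vectorized over r).
#' @export
shear_rate_profile <- function(Q, R, n, r) {
  gw <- wall_shear_rate(Q, R, n)
  gw * (r / R)^(1 / n)
}
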