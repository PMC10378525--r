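# shared fixtures: the studied device and a nominal 9 wt% gelatin solution
default_geometry <- function() channel_geometry()

default_material <- function(k = 5, n = 0.5, b = 0.03) {
  material_properties(power_law_model(k = k, n = n, T_ref = 25, b = b))
}

# closed-form Hagen-Poiseuille pressure drop for the piecewise channel
# (Newtonian fluid, viscosity mu): dp/dz = 8 mu Q / (pi R^4), with the
# conical taper integrated exactly: int R^-4 dz = L/(Rb-Ra)*(Ra^-3-Rb^-3)/3
hagen_poiseuille_dp <- function(geometry, Q, mu) {
  Rb <- geometry$barrel_inner_diameter / 2
  Rn <- geometry$nozzle_diameter / 2
  cone <- geometry$taper_length / (Rn - Rb) * (Rn^-3 - Rb^-3) / (-3)
  8 * mu * Q / pi * (geometry$barrel_length / Rb^4 + cone +
                       geometry$nozzle_land_length / Rn^4)
}

# simpson integration of 2*pi*r*u(r) on a dense grid
section_flow_numeric <- function(Q, R, n, npts = 4001L) {
  r <- seq(0, R, length.out = npts)
  u <- power_law_velocity_profile(Q, R, n, r = r)$u
  f <- 2 * pi * r * u
  h <- r[2L] - r[1L]
  h / 3 * (f[1L] + f[npts] + 4 * sum(f[seq(2L, npts - 1L, by = 2L)]) +
             2 * sum(f[seq(3L, npts - 2L, by = 2L)]))
}
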