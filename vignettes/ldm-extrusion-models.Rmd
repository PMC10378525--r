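---
title: "Process models for low-temperature gelatin extrusion printing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process models for low-temperature gelatin extrusion printing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldmprint)
```

## The process being modeled

Low-temperature deposition manufacturing (LDM) extrudes a warm,
thermo-sensitive gelatin solution through a heated barrel and a fine nozzle
into a chilled chamber, where the deposited line gels and holds its shape.
Whether a print succeeds is decided by a handful of coupled physics:

* the ink is **pseudoplastic** — its apparent viscosity falls with shear
  rate, so it flows readily in the high-shear nozzle while staying stiff on
  the bed;
* the ink **gels near 31 °C**, so the temperature history between barrel and
  outlet decides whether it jams in the nozzle (too cold) or slumps on the
  bed (too warm);
* the deposited **line width** is set by the balance between how fast
  material is pushed in (piston/inlet velocity $v_j$) and how fast the head
  travels (print speed $v_c$).

`ldmprint` implements each of these as a small, testable model, and the
`analysis/` scripts chain them into the study's workflow.

## Rheology

The constitutive model is the power law
$$\eta_a = \tau/\dot\gamma = k\,\dot\gamma^{\,n-1},$$
with consistency coefficient $k$ (Pa·s$^n$) and rheological index $n$
(dimensionless; $n<1$ is shear thinning). Above the gel point an optional
exponential factor $k_{\mathrm{eff}} = k\,e^{-b(T-T_{\mathrm{ref}})}$
captures thermal thinning; $b$ (1/°C) defaults to 0 and is set to 0.03 1/°C
for the nominal 9 wt% ink, a mild 3 %/°C thinning consistent with the
measured ordering (warmer sweeps sit strictly below cooler ones) — the
source experiments never tabulate $k$, $n$ or $b$, so these serve as
illustrative, not calibrated, values.

`fit_power_law()` uses ordinary least squares of $\ln\eta$ on
$\ln\dot\gamma$ (slope $n-1$, intercept $\ln k$). The log-linear form is
closed-form, reproducible, and exact on power-law data; a nonlinear
refinement would only reweight the noise model and is deliberately not the
default.

Two gel-point detectors are provided:

* **Viscosity mutation** (`gel_point_from_viscosity()`): the temperature of
  maximum absolute slope of the viscosity–temperature ramp after a centered
  moving average (window 3 samples by default). A ramp whose maximum slope
  is not at least 3× the median slope is rejected as having no distinct
  mutation rather than returning an arbitrary extremum; both the window and
  the distinctness ratio are arguments.
* **Modulus crossover** (`gel_point_from_crossover()`): linear interpolation
  of the temperature where $G' = G''$, i.e. where the loss tangent crosses 1.
  Multiple sign changes raise an ambiguity error listing the candidates.

On the loss tangent: the applied literature this package follows prints
"$\tan\delta = G'/G''$" yet classifies $\tan\delta < 1$ as elastic, which is
only coherent with the standard definition $\tan\delta = G''/G'$.
`loss_tangent()` computes $G''/G'$ and documents the discrepancy rather than
silently following the printed ratio.

## Natural convection

Heat leaves the exposed metal surfaces by laminar natural convection. The
implemented chain is the textbook correlation
$$Gr = \frac{\beta g \Delta T \rho^2 L^3}{\mu^2},\qquad
  Pr = \frac{c_p \mu}{k},\qquad
  Nu = c\,(Gr\,Pr)^m,\qquad
  h_c = \frac{Nu\,k}{L},$$
with $c = 0.59$, $m = 0.25$ (vertical laminar case — the barrel stands
vertically) and characteristic length $L = 0.045$ m (the heater-sleeve
height). The source text's own statement of the defining relation garbles
$h_c$ and $Nu$ (it prints $h_c = Nu\,L$ and swaps their descriptions); the
dimensionally consistent standard form above is implemented. Air properties
come from a built-in dry-air table (250–350 K, linear interpolation,
$\beta = 1/T_{\mathrm{film}}$) because no property values are given in the
source. At the nominal operating point (30 °C surface, 5 °C chamber) this
yields $h_c \approx 7.4$ W/(m²·K).

## The channel simulator

The reference study solved the full conjugate 3D problem with a ~10M-element
commercial FEM. This package deliberately replaces that with a desk-scale
quasi-1D model that preserves every reported trend; exact field values of
the 3D solution are out of scope by design.

**Flow.** With speeds below 0.1 mm/s in the barrel, inertia and gravity are
negligible and the flow is laminar and fully developed at every station
(lubrication theory). The velocity profile in a section of radius $R$ is the
power-law pipe profile
$$u(r) = \frac{3n+1}{n+1}\,\frac{Q}{\pi R^2}
  \left[1 - (r/R)^{(n+1)/n}\right],$$
whose shape depends only on $n$, so the velocity field is steady and mass
conservation holds by construction. The wall shear rate carries the
Rabinowitsch–Mooney factor $\frac{3n+1}{4n}\cdot\frac{4Q}{\pi R^3}$, and the
pressure gradient follows from the wall force balance
$-dp/dz = 2\tau_w/R$.

**Pressure integration.** Within each axial interval the consistency is
evaluated at the midpoint temperature and the geometric factor
$\int R(z)^{-(3n+1)}dz$ is integrated in closed form (the radius is
piecewise linear). Plain trapezoid quadrature is grossly inaccurate across
the taper, where $R^{-4}$ varies by four orders of magnitude; the
closed-form segment integral makes the isothermal Newtonian case agree with
the piecewise Hagen–Poiseuille sum to machine precision on any grid whose
nodes include the section junctions, and makes $\Delta p$ essentially
grid-independent.

**Heat.** Temperature obeys axisymmetric advection–diffusion
$$\rho c_p\left(\frac{\partial T}{\partial t}
  + u_z \frac{\partial T}{\partial z}\right)
  = k\left(\frac{1}{r}\frac{\partial}{\partial r}
  \left(r\frac{\partial T}{\partial r}\right)
  + \frac{\partial^2 T}{\partial z^2}\right).$$
The radial coordinate is normalized, $\zeta = r/R(z)$. For self-similar
profiles the stream-function fraction through $\zeta$ is the same at every
station, so lines of constant $\zeta$ approximate streamlines; advecting
along them at the local axial speed absorbs the taper's radial velocity
without solving for it. The metric cross-terms this neglects are confined to
the short (5 mm) taper.

Boundary conditions: the material enters at its initial temperature
(Dirichlet at the inlet and as initial field); along the jacketed barrel the
wall is a Dirichlet boundary at the thermostat-driven wall temperature;
below the jacket (taper, land, unjacketed barrel) the wall loses heat to the
chamber through the convection module's $h_c$, frozen at the run's nominal
film temperature ($h_c \propto \Delta T^{1/4}$ varies weakly); the outlet is
advective. Viscous dissipation is neglected (mm/s speeds), and conduction
into the fixed block is lumped into the ambient-side loss rather than
resolved — the block's 13.5 °C initial temperature is carried for
bookkeeping only.

**Thermostat.** The heater control reproduces the measured bang-bang logic:
stop heating when the wall thermocouple exceeds 32 °C, start below 30 °C,
hold otherwise. The jacketed wall relaxes first-order (time constant 30 s)
toward the 45 °C jacket when heating and toward ambient when not, so the
quasi-steady wall rides the 30–32 °C band around the measured 31 °C outer
wall temperature.

**Scheme.** Explicit first-order upwind for axial advection with the time
step fixed by a CFL check (80 % of the bound by default; exceeding it is an
error that names the admissible step), explicit central axial diffusion, and
implicit radial diffusion solved by a batched Thomas algorithm whose
factorization is precomputed per column (geometry and $dt$ are fixed, so the
tridiagonal operators are constant in time; only the Dirichlet right-hand
side moves with the thermostat). The implicit radial direction matters
because the nozzle's fine radial spacing would otherwise bound $dt$
quadratically.

**Viscosity field.** $\eta = k_{\mathrm{eff}}(T)\,\dot\gamma^{\,n-1}$
evaluated pointwise with the shear rate floored at $10^{-3}$ s$^{-1}$
(configurable): the power law diverges on the centerline as
$\dot\gamma\to 0$ for $n<1$, and the floor only affects a thin axis region
that carries no shear stress.

**Problem sizes.** The analysis scripts and tests run 17 radial × 59 axial
nodes (1 mm axial spacing with nodes on both section junctions) for 450 s of
process time per operating point, with a 33 × 117 refinement for the
convergence check; halving the spacings moves the inlet–outlet pressure
difference and the outlet mean temperature by under 1 %, which is the
package's accuracy target for trend comparisons. A 450 s horizon covers the
radial-diffusion time of the barrel (~350 s), after which the outlet
temperature is flat to within a few hundredths of a degree.

## Deposition matching

The deposited line cross-section is modeled as a **stadium**: a rectangle of
height $h$ (layer thickness) capped by two half-discs of diameter $h$,
$A = (w-h)h + \pi h^2/4$. (The source text calls the section "elliptical
flat", but only the stadium area is consistent with its own algebra.)
Equating extruded flux $v_j \pi d_1^2/4$ to deposited flux $v_c A$ gives the
theoretical width
$$d_2 = \frac{v_j \pi d_1^2}{4 v_c h} + \frac{(4-\pi)h}{4},$$
affine in $v_j$, and the exact speed ratio
$k = \pi d_1^2 / (4 d_2 h - 4h^2 + \pi h^2)$ with $v_c = k\,v_j$.

Real lines run wider than the volume balance predicts at low speed (die
swell, spreading before gelation), so the model is corrected empirically:
OLS fits the actual width law $d_3(v_j)$, the width error
$D(v_j) = d_3 - d_2$ is their difference (also affine), and substituting
$d_2 = d_3 - D$ into the speed ratio yields the corrected factor
$$k_1 = \frac{\pi d_1^2}
  {4 h d_2 + (\pi - 4) h^2 - 4 a_D h + 4 b_D h\, v_j},$$
where $D = a_D - b_D v_j$. Solving $v_c = k_1(v_j)\,v_j$ for $v_j$ is a
closed-form linear solve. `corrected_k1()` and `optimal_inlet_velocity()`
take either a fitted calibration or the published rounded constants
($4a_D = 4.14$, $4b_D = 104.78$), the latter reproducing the published
optimum of 0.0242 mm/s for a 2 mm line at 5 mm/s digit for digit.

Two documented inconsistencies in the source are handled explicitly rather
than silently: the stated layer thickness 0.3 mm reproduces none of the
printed widths or regression coefficients while 0.5 mm reproduces all of
them, so 0.5 mm is used for reproduction (both values are exposed in
`fixture_paper_inputs()`, labeled); and refitting the four printed
measurement pairs gives a slope ≈0.15 % away from the printed law — the
published fit evidently used unrounded inputs — which is why the calibration
checks carry 0.5–1 % tolerances.

## Synthetic data

The generators produce every input the workflow needs, with the structure
the analyses assume and nothing more:

* `synth_rheogram()`: log-spaced shear rates 0.1–100 s$^{-1}$, consistency
  growing as a power of concentration and falling exponentially with
  temperature, multiplicative lognormal noise (viscosities stay positive,
  matching rheometer exports). Defaults (base $k$ = 5 Pa·s$^n$ at 9 wt%,
  concentration exponent 2.2, $n$ = 0.5, $b$ = 0.03 1/°C) reproduce the
  measured orderings; absolute levels are illustrative since none were
  published.
* `synth_thermal_ramp()`: a smooth exponential sol baseline times a logistic
  surge (default 30×, width 0.8 °C) centered at the 31 °C gel point, sampled
  at 0.1 °C over 0–45 °C. Zero surge gives the featureless ramp the mutation
  detector must reject.
* `synth_oscillatory()`: both moduli decay exponentially with temperature,
  $G'$ faster than $G''$, so they cross exactly once at the gel temperature
  and $\tan\delta$ is monotone — the cleanest realization of the measured
  crossover structure.
* `synth_line_widths()`: additive Gaussian noise on an affine width law
  (lengths measured off micrographs), seed-reproducible.

What passing tests on these generators do **not** show: real rheometer
artifacts (inertia, slip, thixotropy), non-power-law behavior outside
0.1–100 s$^{-1}$, the gradual gelation kinetics between the fast- and
slow-gel regimes, or image-measurement bias in line widths. The generators
are structural stand-ins, so quantitative recovery results transfer to real
data only to the extent the real data match those structures.

## Numerical and design choices

* Degenerate inputs fail loudly: nonpositive shear rates, radii or moduli,
  widths below the layer thickness, coarse pressure grids (<10 stations),
  thermostat bands out of order, and time steps beyond the stability bound
  all raise errors naming the offense.
* The taper and nozzle-land lengths (5 mm and 3 mm) are not printed in the
  source; they are configurable defaults constrained by the printed bore,
  outlet diameter and total length.
* Gelatin-solution thermal properties are not printed either; water-like
  defaults (ρ = 1000 kg/m³, $c_p$ = 4000 J/(kg·K), k = 0.55 W/(m·K)) are
  used, overridable in `material_properties()`.
* Ties in the mutation detector resolve to the first maximum (`which.max`);
  with the default dense sampling this is immaterial.
* Column names of all text tables embed units (`width_mm`,
  `shear_rate_1_s`) so tables cannot silently change units between the
  mm-based flow modules and the SI heat-transfer module; conversions happen
  once, inside the simulator.

## Known limitations

* The quasi-1D simulator reproduces orderings and shapes, not the 3D FEM's
  point values; outlet temperatures land ~1–3 °C above the reference
  values because conjugate conduction into the cold fixed block is lumped
  into a convective loss.
* The power-law model has no yield stress or thixotropy; below the gel point
  the material is still treated as a (very viscous) fluid.
* Natural convection only: no radiation, no forced draft, laminar
  correlation constants.
* The width correction is calibrated on four points at one print speed and
  one layer height; extrapolating $k_1$ far from that window inherits the
  regression's uncertainty.
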