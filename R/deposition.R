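#' Stadium cross-section area of a deposited line
#'
#' A deposited line of width `w` and layer thickness `h` is modeled as a
#' flattened section: a rectangle of width `w - h` capped by two half-discs
#' of diameter `h`, so `A = (w - h) h + pi h^2 / 4`. At `w = h` the section
#' degenerates to a circle.
#'
#' @param width Line width, mm; must be >= `h`.
#' @param h Layer thickness, mm, > 0.
#' @return Area in mm^2.
#' @export
stadium_area <- function(width, h) {
  if (any(h <= 0)) stop("layer thickness h must be positive")
  if (any(width < h)) stop("width must be at least the layer thickness h")
  (width - h) * h + pi * h^2 / 4
}

#' Theoretical deposited line width from volume balance
#'
#' Extruded volume per unit time (`v_j pi d1^2/4`) equals deposited volume
#' per unit time (`v_c` times the stadium area), solved for the width:
#' \deqn{d_2 = \frac{v_j \pi d_1^2}{4 v_c h} + \frac{(4-\pi) h}{4}.}
#'
#' @param v_j Inlet (piston) velocity, mm/s.
#' @param v_c Deposition (print-head travel) speed, mm/s.
#' @param d1 Barrel inner diameter, mm.
#' @param h Layer thickness, mm.
#' @return Width d2 in mm. When the result falls below `h` (line thinner
#'   than the layer: the stadium degenerates) it is returned with a warning.
#' @export
theoretical_width <- function(v_j, v_c, d1, h) {
  if (any(c(v_j, v_c, d1, h) <= 0)) stop("all inputs must be positive")
  d2 <- v_j * pi * d1^2 / (4 * v_c * h) + (4 - pi) * h / 4
  if (any(d2 < h)) warning("theoretical width below layer thickness: unphysical stadium section")
  d2
}

#' Volume-balance speed ratio k
#'
#' The ratio `v_c / v_j` that exactly balances extrusion and deposition for
#' a target width `d2`:
#' \deqn{k = \frac{\pi d_1^2}{4 d_2 h - 4 h^2 + \pi h^2}.}
#'
#' @param d1 Barrel inner diameter, mm.
#' @param d2 Target line width, mm, >= h.
#' @param h Layer thickness, mm.
#' @return Dimensionless k with `v_c = k v_j` at exact volume balance.
#' @export
speed_ratio_k <- function(d1, d2, h) {
  den <- 4 * d2 * h - 4 * h^2 + pi * h^2
  if (any(den <= 0)) stop("nonpositive denominator: d2 too small for layer thickness h")
  pi * d1^2 / den
}

#' Affine width-velocity law
#'
#' @param intercept mm.
#' @param slope mm per (mm/s).
#' @return A `linear_law` list with a `predict`-style evaluation via
#'   [eval_law()].
#' @export
linear_law <- function(intercept, slope) {
  if (!all(is.finite(c(intercept, slope)))) stop("law coefficients must be finite")
  structure(list(intercept = intercept, slope = slope), class = "linear_law")
}

#' Evaluate an affine law
#' @param law A [linear_law()].
#' @param v_j Inlet velocities, mm/s.
#' @return Predicted widths, mm.
#' @export
eval_law <- function(law, v_j) law$intercept + law$slope * v_j

#' @export
print.linear_law <- function(x, ...) {
  cat(sprintf("width = %.4f %+.4f * v_j  [mm; v_j in mm/s]\n", x$intercept, x$slope))
  invisible(x)
}

#' Measured line widths at inlet velocities
#'
#' @param inlet_velocity Inlet velocities, mm/s, positive.
#' @param width Measured line widths, mm, positive.
#' @return A `width_measurements` data.frame.
#' @export
width_measurements <- function(inlet_velocity, width) {
  if (length(inlet_velocity) != length(width)) stop("lengths differ")
  if (any(inlet_velocity <= 0) || any(width <= 0)) stop("velocities and widths must be positive")
  structure(data.frame(inlet_velocity = inlet_velocity, width = width),
            class = c("width_measurements", "data.frame"))
}

#' Fit the measured width-velocity law by OLS
#'
#' @param measurements A [width_measurements()] (or data.frame with columns
#'   `inlet_velocity`, `width`); at least two distinct velocities.
#' @return A [linear_law()] carrying the `lm` fit as attribute `fit`.
#' @export
fit_width_law <- function(measurements) {
  v <- measurements$inlet_velocity; w <- measurements$width
  if (length(unique(v)) < 2L) stop("need at least two distinct inlet velocities to fit a line")
  fit <- stats::lm(w ~ v)
  law <- linear_law(unname(stats::coef(fit)[1L]), unname(stats::coef(fit)[2L]))
  attr(law, "fit") <- fit
  law
}

#' Calibrate the width model against measurements
#'
#' Fits the actual width law `d3(v_j)` by OLS, derives the theoretical law
#' `d2(v_j)` analytically from the volume balance (which is already affine
#' in `v_j`: slope `pi d1^2 / (4 v_c h)`, intercept `(4 - pi) h / 4`), and
#' forms the width-error law `D(v_j) = d3(v_j) - d2(v_j)` as their
#' coefficientwise difference.
#'
#' @param measurements A [width_measurements()].
#' @param v_c Deposition speed, mm/s.
#' @param d1 Barrel inner diameter, mm.
#' @param h Layer thickness, mm.
#' @return A `width_calibration`: list with `actual_law`, `theoretical_law`,
#'   `error_law`, and the inputs.
#' @export
calibrate_widths <- function(measurements, v_c, d1, h) {
  actual <- fit_width_law(measurements)
  theo <- linear_law((4 - pi) * h / 4, pi * d1^2 / (4 * v_c * h))
  err <- linear_law(actual$intercept - theo$intercept, actual$slope - theo$slope)
  structure(list(actual_law = actual, theoretical_law = theo, error_law = err,
                 v_c = v_c, d1 = d1, h = h, measurements = measurements),
            class = "width_calibration")
}

#' @export
print.width_calibration <- function(x, ...) {
  cat("Width calibration (mm, v_j in mm/s):\n")
  cat("  actual      d3 = "); print(x$actual_law)
  cat("  theoretical d2 = "); print(x$theoretical_law)
  cat("  error        D = "); print(x$error_law)
  invisible(x)
}

# The matching model's published correction constants: the error-law
# intercept enters as 4*1.0345 (printed rounded to 4.14) and its velocity
# coefficient as 4*26.195 = 104.78.
.paper_error_constants <- list(four_aD = 4.14, four_bD = 104.78)

#' Corrected speed-ratio factor k1
#'
#' Generalization of the volume-balance ratio that absorbs the empirical
#' width error `D(v_j) = a_D - b_D v_j` (a decreasing function of inlet
#' velocity):
#' \deqn{k_1 = \frac{\pi d_1^2}{4 h d_2 + (\pi - 4) h^2 - 4 a_D h + 4 b_D h v_j}.}
#' With a zero error law this reduces exactly to [speed_ratio_k()]. In
#' `mode = "paper_constants"` the published rounded constants
#' `4 a_D = 4.14` and `4 b_D = 104.78` are used verbatim so the published
#' worked example reproduces digit for digit.
#'
#' @param d1 Barrel inner diameter, mm.
#' @param h Layer thickness, mm.
#' @param target_width Desired line width d2, mm.
#' @param v_j Inlet velocity, mm/s.
#' @param error_law A [linear_law()] for D (used in `mode = "fitted"`).
#' @param mode `"fitted"` (use `error_law`) or `"paper_constants"`.
#' @return Dimensionless k1 with `v_c = k1 v_j` at the corrected match.
#' @export
corrected_k1 <- function(d1, h, target_width, v_j, error_law = NULL,
                         mode = c("fitted", "paper_constants")) {
  mode <- match.arg(mode)
  if (mode == "paper_constants") {
    fa <- .paper_error_constants$four_aD
    fb <- .paper_error_constants$four_bD
  } else {
    if (is.null(error_law)) stop("mode='fitted' requires an error_law")
    fa <- 4 * error_law$intercept
    fb <- 4 * (-error_law$slope)
  }
  den <- 4 * h * target_width + (pi - 4) * h^2 - fa * h + fb * h * v_j
  if (any(den <= 0)) stop("nonpositive denominator in corrected speed ratio")
  pi * d1^2 / den
}

#' Optimal inlet velocity for a target line width
#'
#' Solves the corrected matching relation `v_c = k1(v_j) v_j` for `v_j`.
#' After clearing the denominator the relation is affine in `v_j`, so the
#' solution is closed form:
#' \deqn{v_j = \frac{v_c (4 h d_2 + (\pi-4) h^2 - 4 a_D h)}{\pi d_1^2 - 4 b_D h v_c}.}
#'
#' @param target_width Desired line width, mm, > h.
#' @param v_c Deposition speed, mm/s.
#' @param calibration A `width_calibration` (its `error_law`, `d1`, `h` are
#'   used) or `NULL` with `mode = "paper_constants"`.
#' @param d1,h Geometry, mm; default from `calibration`.
#' @param mode `"fitted"` or `"paper_constants"` (see [corrected_k1()]).
#' @return Optimal inlet velocity, mm/s.
#' @export
optimal_inlet_velocity <- function(target_width, v_c, calibration = NULL,
                                   d1 = calibration$d1, h = calibration$h,
                                   mode = c("fitted", "paper_constants")) {
  mode <- match.arg(mode)
  if (target_width <= h) stop("target_width must exceed the layer thickness")
  if (mode == "paper_constants") {
    fa <- .paper_error_constants$four_aD
    fb <- .paper_error_constants$four_bD
  } else {
    if (is.null(calibration)) stop("mode='fitted' requires a calibration")
    fa <- 4 * calibration$error_law$intercept
    fb <- 4 * (-calibration$error_law$slope)
  }
  num <- v_c * (4 * h * target_width + (pi - 4) * h^2 - fa * h)
  den <- pi * d1^2 - fb * h * v_c
  v_j <- num / den
  if (!is.finite(v_j) || v_j <= 0) stop("no positive inlet velocity solves the matching relation")
  v_j
}
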