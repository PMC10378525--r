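test_that("stadium cross-section area", {
  expect_equal(stadium_area(2, 0.5), 0.75 + pi / 16)
  expect_equal(stadium_area(0.5, 0.5), pi * 0.25^2)        # degenerate circle
  w <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(stadium_area(w, 0.5)) > 0))
  expect_error(stadium_area(0.3, 0.5), "at least")
  expect_error(stadium_area(2, -1), "positive")
})

test_that("theoretical width reproduces the published worked values (h = 0.5 mm)", {
  vj <- c(0.0156, 0.0313, 0.0469, 0.0625)
  d2 <- theoretical_width(vj, v_c = 5, d1 = 14, h = 0.5)
  printed <- c(1.068, 2.034, 2.99, 3.955)
  # tolerance: one unit in each value's last printed digit
  tol <- c(0.001, 0.001, 0.01, 0.001)
  expect_true(all(abs(d2 - printed) <= tol))
  # degenerate case: flux matching a circular bead of diameter h gives d2 = h
  h <- 0.5; v_c <- 5
  vj_star <- v_c * (pi * h^2 / 4) / (pi * 14^2 / 4)
  expect_equal(theoretical_width(vj_star, v_c, 14, h), h)
  expect_warning(theoretical_width(vj_star / 2, v_c, 14, h), "below layer thickness")
})

test_that("speed ratio k inverts the width law (volume balance identity)", {
  expect_equal(speed_ratio_k(14, 2, 0.5), pi * 196 / (4 * 2 * 0.5 - 4 * 0.25 + pi * 0.25))
  expect_equal(speed_ratio_k(14, 2, 0.5), 162.66, tolerance = 1e-4)
  # d2 = h degenerates to (d1/h)^2
  expect_equal(speed_ratio_k(14, 0.5, 0.5), (14 / 0.5)^2)
  # round trip: k(d1, d2(v_j), h) * v_j = v_c for random valid inputs
  set.seed(11)
  for (i in 1:30) {
    d1 <- runif(1, 5, 20); h <- runif(1, 0.2, 1)
    v_c <- runif(1, 1, 10); v_j <- runif(1, 0.01, 0.1)
    d2 <- suppressWarnings(theoretical_width(v_j, v_c, d1, h))
    if (d2 >= h) {
      expect_equal(speed_ratio_k(d1, d2, h) * v_j, v_c, tolerance = 1e-9)
      # volume balance: extruded flux equals deposited stadium flux
      expect_equal(v_j * pi * d1^2 / 4, v_c * stadium_area(d2, h), tolerance = 1e-9)
    }
  }
  expect_error(speed_ratio_k(14, 0.01, 0.5), "denominator")
})

test_that("OLS width law recovers the published regression", {
  fx <- fixture_paper_inputs()
  law <- fit_width_law(fx$measurements)
  expect_equal(law$slope, 35.3344, tolerance = 0.01)      # within 1%
  expect_equal(law$intercept, 1.1415, tolerance = 0.01)
  # two points: exact interpolating line
  two <- width_measurements(c(0.02, 0.04), c(1, 2))
  law2 <- fit_width_law(two)
  expect_equal(eval_law(law2, c(0.02, 0.04)), c(1, 2))
  # exact recovery of a noiseless law
  tl <- linear_law(1.2, 30)
  m0 <- synth_line_widths(tl, c(0.01, 0.03, 0.05, 0.07), noise_sd = 0)
  law3 <- fit_width_law(m0)
  expect_equal(law3$intercept, 1.2, tolerance = 1e-12)
  expect_equal(law3$slope, 30, tolerance = 1e-10)
  expect_error(fit_width_law(width_measurements(c(0.02, 0.02), c(1, 2))), "distinct")
})

test_that("calibration reproduces the published laws and error line", {
  fx <- fixture_paper_inputs()
  cal <- calibrate_widths(fx$measurements, v_c = fx$v_c, d1 = 14, h = fx$h)
  expect_lt(abs(cal$theoretical_law$slope - 61.529) / 61.529, 0.005)   # 0.5%
  expect_lt(abs(cal$error_law$slope - (-26.195)) / 26.195, 0.005)
  # error law is the componentwise difference of the fitted laws
  expect_equal(cal$error_law$intercept,
               cal$actual_law$intercept - cal$theoretical_law$intercept,
               tolerance = 1e-12)
  # measurements exactly on the theoretical law calibrate to zero error
  v <- c(0.0156, 0.0313, 0.0469, 0.0625)
  exact <- width_measurements(v, theoretical_width(v, 5, 14, 0.5))
  cal0 <- calibrate_widths(exact, 5, 14, 0.5)
  expect_equal(cal0$error_law$intercept, 0, tolerance = 1e-10)
  expect_equal(cal0$error_law$slope, 0, tolerance = 1e-8)
  # a constant offset appears only in the error intercept (OLS linearity)
  off <- width_measurements(v, theoretical_width(v, 5, 14, 0.5) + 0.3)
  cal_off <- calibrate_widths(off, 5, 14, 0.5)
  expect_equal(cal_off$error_law$intercept, 0.3, tolerance = 1e-10)
  expect_equal(cal_off$error_law$slope, 0, tolerance = 1e-8)
})

test_that("calibration recovers a known affine perturbation, also under noise", {
  v <- seq(0.01, 0.08, length.out = 8)
  truth <- c(intercept = 0.9, slope = -20)
  base <- theoretical_width(v, 5, 14, 0.5)
  clean <- width_measurements(v, base + truth["intercept"] + truth["slope"] * v)
  cal <- calibrate_widths(clean, 5, 14, 0.5)
  expect_equal(cal$error_law$intercept, 0.9, tolerance = 1e-6)
  expect_equal(cal$error_law$slope, -20, tolerance = 1e-6)
  # 2% multiplicative noise: recovered coefficients within 2 SE
  set.seed(31)
  noisy <- width_measurements(v, (base + 0.9 - 20 * v) * (1 + stats::rnorm(8, 0, 0.02)))
  caln <- calibrate_widths(noisy, 5, 14, 0.5)
  se <- summary(attr(caln$actual_law, "fit"))$coefficients[, "Std. Error"]
  expect_lt(abs(caln$error_law$intercept - 0.9), 2 * se[1L])
  expect_lt(abs(caln$error_law$slope - (-20)), 2 * se[2L])
})

test_that("corrected k1 matches the published worked example and its limits", {
  # published constants: matching a 2 mm line at v_j = 0.0242 gives v_c ~ 5
  k1 <- corrected_k1(14, 0.5, target_width = 2, v_j = 0.0242, mode = "paper_constants")
  expect_equal(k1 * 0.0242, 5, tolerance = 0.005)  # v_j printed rounded to 4 decimals
  # zero error law reduces k1 to the volume-balance k
  zero <- linear_law(0, 0)
  expect_equal(corrected_k1(14, 0.5, 2, 0.03, error_law = zero, mode = "fitted"),
               speed_ratio_k(14, 2, 0.5))
  # fitted mode from the four published pairs agrees with the printed constants
  fx <- fixture_paper_inputs()
  cal <- calibrate_widths(fx$measurements, fx$v_c, 14, fx$h)
  k_fit <- corrected_k1(14, 0.5, 2, 0.0242, error_law = cal$error_law, mode = "fitted")
  expect_equal(k_fit / k1, 1, tolerance = 0.005)
})

test_that("optimal inlet velocity solves the corrected matching relation", {
  vj <- optimal_inlet_velocity(2, 5, d1 = 14, h = 0.5, mode = "paper_constants")
  expect_equal(round(vj, 4), 0.0242)
  # the solution satisfies v_c = k1(v_j) v_j exactly
  expect_equal(corrected_k1(14, 0.5, 2, vj, mode = "paper_constants") * vj, 5,
               tolerance = 1e-12)
  # zero correction: inverse identity with the theoretical width
  zero_cal <- list(error_law = linear_law(0, 0), d1 = 14, h = 0.5)
  class(zero_cal) <- "width_calibration"
  v_star <- 0.033
  target <- theoretical_width(v_star, 5, 14, 0.5)
  expect_equal(optimal_inlet_velocity(target, 5, zero_cal), v_star, tolerance = 1e-12)
  # strictly increasing in the target width (above the correction model's
  # zero-velocity width, the actual-law intercept ~1.14 mm)
  vs <- vapply(seq(1.25, 3.5, by = 0.25), function(w)
    optimal_inlet_velocity(w, 5, d1 = 14, h = 0.5, mode = "paper_constants"),
    numeric(1))
  expect_true(all(diff(vs) > 0))
  expect_error(optimal_inlet_velocity(0.3, 5, d1 = 14, h = 0.5,
                                      mode = "paper_constants"), "exceed")
})

test_that("self-consistency: the corrected optimum deposits a ~2 mm line", {
  fx <- fixture_paper_inputs()
  vj <- optimal_inlet_velocity(2, 5, d1 = 14, h = 0.5, mode = "paper_constants")
  predicted <- eval_law(fx$actual_law_printed, vj)
  expect_equal(predicted, 2, tolerance = 0.005)
})
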