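#!/usr/bin/env Rscript
# Line-width calibration and extrusion/print speed matching.
#
# Uses the published experiment: four deposition lines printed at inlet
# velocities 0.0156-0.0625 mm/s with 5 mm/s print speed, 0.5 mm layers,
# 14 mm barrel. Fits the actual width law, derives the theoretical law from
# volume balance, forms the width-error correction, and solves for the
# inlet velocity that deposits a 2 mm line.

suppressPackageStartupMessages(library(ldmprint))
dir.create("results", showWarnings = FALSE)

fx <- fixture_paper_inputs()
cal <- calibrate_widths(fx$measurements, v_c = fx$v_c,
                        d1 = fx$geometry$barrel_inner_diameter, h = fx$h)
print(cal)

laws <- data.frame(
  law = c("actual_fit", "theoretical", "error",
          "actual_published", "theoretical_published", "error_published"),
  intercept_mm = c(cal$actual_law$intercept, cal$theoretical_law$intercept,
                   cal$error_law$intercept, fx$actual_law_printed$intercept,
                   fx$theoretical_law_printed$intercept,
                   fx$error_law_printed$intercept),
  slope_mm_per_mm_s = c(cal$actual_law$slope, cal$theoretical_law$slope,
                        cal$error_law$slope, fx$actual_law_printed$slope,
                        fx$theoretical_law_printed$slope,
                        fx$error_law_printed$slope))
utils::write.csv(laws, "results/width_laws.csv", row.names = FALSE)

vj_fit <- optimal_inlet_velocity(2, fx$v_c, cal, mode = "fitted")
vj_pub <- optimal_inlet_velocity(2, fx$v_c, d1 = 14, h = fx$h,
                                 mode = "paper_constants")
log_line("optimal v_j for a 2 mm line at 5 mm/s: %.4f mm/s (fitted) vs %.4f mm/s (published constants)",
         vj_fit, vj_pub)
log_line("corrected speed ratio k1 at the optimum: %.1f (volume-balance k would give %.1f)",
         corrected_k1(14, fx$h, 2, vj_pub, mode = "paper_constants"),
         speed_ratio_k(14, 2, fx$h))

opt <- data.frame(target_width_mm = 2, print_speed_mm_s = fx$v_c,
                  vj_fitted_mm_s = vj_fit, vj_published_mm_s = vj_pub)
write_table(opt, "results/optimal_inlet_velocity.csv",
            table_schema(names(opt), c("mm", "mm/s", "mm/s", "mm/s")))
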