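#!/usr/bin/env Rscript
# Natural-convection heat-transfer coefficient of the exposed print head.
#
# The barrel sits vertically in a 5 degC chamber; heat leaves the exposed
# metal by laminar natural convection, Nu = 0.59 (Gr Pr)^0.25 with the
# 45 mm sleeve height as characteristic length. This script tabulates h_c
# over the surface temperatures the process traverses.

suppressPackageStartupMessages(library(ldmprint))
dir.create("results", showWarnings = FALSE)

cfg <- convection_config(c = 0.59, m = 0.25, L = 0.045)
ambient <- 5
surface <- seq(10, 45, by = 5)

rows <- do.call(rbind, lapply(surface, function(Ts) {
  props <- air_properties((Ts + ambient) / 2)
  Gr <- grashof(props, Ts - ambient, cfg$L, cfg$g)
  Pr <- prandtl(props)
  Nu <- nusselt(Gr, Pr, cfg)
  data.frame(surface_T_C = Ts, Gr = Gr, Pr = Pr, Nu = Nu,
             h_W_m2K = convective_coefficient(Nu, props$k_cond, cfg$L))
}))
write_table(rows, "results/convection_coefficients.csv",
            table_schema(names(rows), c("degC", "-", "-", "-", "W/(m2.K)")))

log_line("h_c spans %.2f-%.2f W/(m2.K) over surface temperatures %g-%g degC",
         min(rows$h_W_m2K), max(rows$h_W_m2K), min(surface), max(surface))
log_line("at the 30 degC operating point h_c = %.2f W/(m2.K)",
         natural_convection_h(30, ambient, cfg))
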