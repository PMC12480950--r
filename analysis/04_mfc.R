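#!/usr/bin/env Rscript
# Stage 4: MFC polarization sweep -> power-density curve, maximum power
# density, and the Thevenin internal-resistance diagnostic.

library(sedshuttle)

dat <- read.csv("results/data/polarization.csv")
sw <- polarization_sweep(dat$R_ohm, dat$V_volt, dat$area_m2[1],
                         dat$sample_id[1])
curve <- power_density_curve(sw)
write.csv(curve, "results/power_density_curve.csv", row.names = FALSE)

mp <- max_power_density(sw)
cat(sprintf("MPD = %.1f uW/m^2 at R_ext = %d ohm\n", mp$mpd,
            mp$resistance_at_max))

est <- estimate_internal_resistance(sw)
if (est$converged) {
  cat(sprintf("Thevenin fit: Voc = %.3f V, Rint = %.0f ohm (closed-form MPD %.1f uW/m^2)\n",
              est$voc, est$rint, est$voc^2 / (4 * est$rint * sw$anode_area) * 1e6))
} else {
  cat("Thevenin fit did not converge:", est$flags, "\n")
}
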