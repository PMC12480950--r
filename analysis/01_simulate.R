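#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs (site survey, paired
# incubations, headspace samples, polarization sweep, qPCR Ct table) and
# write them as CSV under results/data/.
#
# The survey emulates a 12-site field campaign: humic substances (HS)
# spanning 9.5-230.1 mg/g, HA dominating HS, maximum power density (MPD)
# coupled to HS, and excess N2 coupled to MPD only.

library(sedshuttle)

seed <- 20260101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

survey <- generate_survey(survey_config(seed = seed))
write.csv(survey, file.path(out, "survey.csv"), row.names = FALSE)
cat(sprintf("survey: %d sites, HS %.1f-%.1f mg/g, MPD %.2f-%.2f uW/m^2\n",
            nrow(survey), min(survey$hs), max(survey$hs),
            min(survey$mpd), max(survey$mpd)))

# paired Blank/HS_C incubations whose enhancement decays with native HS
vials <- generate_incubation(
  incubation_config(n_pairs = 8, native_hs = sort(survey$hs)[1:8],
                    seed = seed + 1L))
inc_rows <- do.call(rbind, lapply(names(vials), function(nm) {
  v <- vials[[nm]]
  data.frame(pair_id = v$pair_id, group = v$group_label, time_h = v$times,
             n29_umol_L = v$conc29, n30_umol_L = v$conc30, fn = v$fn,
             dry_mass_g = v$sediment_dry_mass, vol_mL = v$liquid_volume)
}))
write.csv(inc_rows, file.path(out, "incubations.csv"), row.names = FALSE)
cat(sprintf("incubations: %d vials x %d observations\n", length(vials),
            length(vials[[1]]$times)))

hs <- generate_headspace(n = 12, true_cw = 0.02, noise_sd = 5e-4,
                         seed = seed + 2L)
write.csv(data.frame(Cg_umol_L = hs$headspace_conc,
                     Cair_umol_L = hs$air_conc, Vg_mL = hs$gas_volume,
                     Vl_mL = hs$liquid_volume, T_equil_K = hs$temperature,
                     K0 = hs$solubility_coeff, true_cw = attr(hs, "truth")),
          file.path(out, "headspace.csv"), row.names = FALSE)

sweep <- generate_polarization(voc = 0.4, rint = 800,
                               r_grid = c(100, 200, 400, 800, 1600, 3200,
                                          6400),
                               area = 0.01, noise_sd = 0.003,
                               seed = seed + 3L)
write.csv(data.frame(sample_id = sweep$sample_id,
                     R_ohm = sweep$external_resistance,
                     V_volt = sweep$voltage, area_m2 = sweep$anode_area),
          file.path(out, "polarization.csv"), row.names = FALSE)

ct <- generate_qpcr(seed = seed + 4L)
write.csv(ct, file.path(out, "qpcr_ct.csv"), row.names = FALSE)
cat("wrote survey.csv, incubations.csv, headspace.csv, polarization.csv,",
    "qpcr_ct.csv\n")
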