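#!/usr/bin/env Rscript
# Stage 6: survey-scale driver analysis of excess N2: Spearman screening,
# HS->MPD simple regression, stepwise AIC driver selection with validation,
# and the exponential association of excess N2 with MPD.

library(sedshuttle)

survey <- read.csv("results/data/survey.csv")
cand <- c("mpd", "do_mg_l", "ph", "no3", "nh4", "no2")

sm <- spearman_matrix(survey, c("delta_n2", cand))
cat("Spearman rho with excess N2:\n")
print(round(sm$rho["delta_n2", cand], 3))

hs_mpd <- simple_lr(survey$hs, survey$mpd)
cat(sprintf("HS -> MPD: slope %.3f, R^2 = %.4f, p = %.2e\n",
            hs_mpd$slope, hs_mpd$r_squared, hs_mpd$p_value))

fit <- stepwise_aic_mlr(survey, "delta_n2", cand)
print(fit)
writeLines(fit$log, "results/driver_selection.log")
if (!is.null(fit$coefficients)) {
  write.csv(fit$coefficients, "results/driver_coefficients.csv",
            row.names = FALSE)
}

fe <- exp_association_fit(survey$mpd, survey$delta_n2)
if (fe$converged) {
  cat(sprintf("excess N2 ~ a*exp(b*MPD)+c: b = %.4f, t(%d) = %.2f, one-sided p = %.4f\n",
              fe$b, fe$df, fe$t, fe$p_one_sided))
}
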