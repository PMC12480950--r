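test_that("every generator is a pure function of config + seed", {
  s1 <- generate_survey(survey_config(seed = 21))
  s2 <- generate_survey(survey_config(seed = 21))
  expect_identical(s1, s2)
  i1 <- generate_incubation(incubation_config(seed = 22))
  i2 <- generate_incubation(incubation_config(seed = 22))
  expect_identical(i1, i2)
  q1 <- generate_qpcr(seed = 23)
  q2 <- generate_qpcr(seed = 23)
  expect_identical(q1, q2)
  h1 <- generate_headspace(5, 0.02, noise_sd = 0.001, seed = 24)
  h2 <- generate_headspace(5, 0.02, noise_sd = 0.001, seed = 24)
  expect_identical(h1, h2)
  expect_false(identical(generate_survey(survey_config(seed = 25)), s1))
})

test_that("survey columns respect the configured field structure", {
  sv <- generate_survey(survey_config(seed = 26))
  expect_equal(nrow(sv), 12)
  expect_true(all(sv$hs >= 9.5 & sv$hs <= 230.1))
  expect_true(all(sv$ha_fraction > 0 & sv$ha_fraction <= 1))
  expect_equal(sv$ha + sv$fa, sv$hs, tolerance = 1e-12)
  expect_equal(sv$delta_n2, sv$n2_dissolved -
                 equilibrium_concentration("N2", sv$temp_c + 273.15, 0),
               tolerance = 1e-9)
})

test_that("noise-free coupling gives an exact HS-MPD line", {
  sv <- generate_survey(survey_config(mpd_hs_r2 = 1, seed = 27))
  expect_equal(simple_lr(sv$hs, sv$mpd)$r_squared, 1, tolerance = 1e-12)
})

test_that("HS-MPD coupling calibration hits the configured R2 on average", {
  r2 <- vapply(1:300, function(i) {
    sv <- generate_survey(survey_config(seed = 30000 + i))
    simple_lr(sv$hs, sv$mpd)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.7355), 0.05)
})

test_that("HA dominates HS at roughly the configured share", {
  fr <- unlist(lapply(1:50, function(i)
    generate_survey(survey_config(seed = 31000 + i))$ha_fraction))
  # analytic mean of N(0.928, 0.094) truncated to (0, 1]
  z <- (1 - 0.928) / 0.094
  trunc_mean <- 0.928 - 0.094 * dnorm(z) / pnorm(z)
  expect_lt(abs(mean(fr) - trunc_mean), 0.02)
  expect_gt(mean(fr), 0.85)   # HA still strongly dominant
})

test_that("infeasible coupling targets error out", {
  expect_error(generate_survey(survey_config(mpd_hs_r2 = 0, seed = 1)),
               "R\\^2")
  cfg <- survey_config(seed = 1)
  cfg$mpd_hs_slope <- 0
  expect_error(generate_survey(cfg), "infeasible")
})

test_that("noise-free incubations are inverted exactly by the IPT stage", {
  cfg <- incubation_config(d_rate = 10, a_rate = 5, fn = 0.5, noise_sd = 0,
                           pair_cv = 0, n_pairs = 1, seed = 28)
  vials <- generate_incubation(cfg)
  blank <- analyze_incubation(vials$pair1_Blank)
  expect_equal(blank$partition$d_rate, 10, tolerance = 1e-9)
  expect_equal(blank$partition$a_rate, 5, tolerance = 1e-9)
  hsc <- analyze_incubation(vials$pair1_HS_C)
  expect_equal(hsc$partition$d_rate, 26, tolerance = 1e-9)  # 2.6x
})

test_that("fully labeled incubations put all 29N2 on anammox", {
  cfg <- incubation_config(d_rate = 10, a_rate = 5, fn = 1, noise_sd = 0,
                           pair_cv = 0, n_pairs = 1, seed = 29)
  v <- generate_incubation(cfg)$pair1_Blank
  f29 <- fit_production_rate(v$times, v$conc29)
  expect_equal(f29$slope, 5, tolerance = 1e-9)   # A only: 2D*fn*(1-fn) = 0
})

test_that("HS_C/Blank rate enhancement is recovered near 2.6x under noise", {
  ratios <- vapply(1:200, function(i) {
    v <- generate_incubation(incubation_config(n_pairs = 1,
                                               seed = 32000 + i))
    d_b <- analyze_incubation(v$pair1_Blank)$partition$d_rate
    d_h <- analyze_incubation(v$pair1_HS_C)$partition$d_rate
    d_h / d_b
  }, numeric(1))
  expect_lt(abs(median(ratios) - 2.6) / 2.6, 0.10)
})

test_that("native HS attenuates the realized enhancement", {
  cfg <- incubation_config(n_pairs = 3, noise_sd = 0, pair_cv = 0,
                           native_hs = c(0, 50, 200), seed = 33)
  tr <- attr(generate_incubation(cfg), "truth")
  effs <- vapply(tr[grepl("HS_C", names(tr))], `[[`, numeric(1), "effect")
  expect_equal(unname(effs[1]), 2.6, tolerance = 1e-12)
  expect_true(all(diff(effs) < 0))
  expect_gt(min(effs), 1)
})

test_that("zero-noise headspace samples round-trip exactly", {
  hs <- generate_headspace(10, true_cw = 0.02, noise_sd = 0, seed = 34)
  rec <- headspace_original_concentration(hs)
  expect_equal(rec$cw, rep(0.02, 10), tolerance = 1e-12)
  # headspace forced to ambient air recovers equilibrium water
  s <- headspace_sample(0.0135, 0.0135, 40, 160, 298.15, 0.0248)
  expect_equal(headspace_original_concentration(s)$cw,
               0.0135 * 0.0248 * GAS_CONSTANT_L_ATM * 298.15,
               tolerance = 1e-12)
})

test_that("headspace recovery is unbiased under measurement noise", {
  hs <- generate_headspace(1000, true_cw = 0.02, noise_sd = 0.002, seed = 35)
  rec <- suppressWarnings(headspace_original_concentration(hs))
  expect_lt(abs(mean(rec$cw) - 0.02) / 0.02, 0.02)
})

test_that("polarization generator matches the closed form on-grid", {
  sw <- generate_polarization(0.4, 800, c(200, 400, 800, 1600), 0.01,
                              noise_sd = 0, seed = 36)
  expect_equal(max_power_density(sw)$mpd, 0.4^2 / (4 * 800 * 0.01) * 1e6,
               tolerance = 1e-12)
  coarse <- generate_polarization(0.4, 800, c(150, 3100), 0.01,
                                  noise_sd = 0, seed = 37)
  expect_lt(max_power_density(coarse)$mpd, 0.4^2 / (4 * 800 * 0.01) * 1e6)
})

test_that("qPCR generator recovers configured folds and nulls", {
  tab <- generate_qpcr(true_folds = c(flat = 1, up = 31.5, mid = 7.7),
                       seed = 38)
  gt <- qpcr_gene_table(tab)
  expect_lt(abs(gt$fold_ratio[gt$gene == "flat"] - 1), 0.25)
  rr <- ratio_of_ratios(gt$fold_ratio[gt$gene == "up"],
                        gt$fold_ratio[gt$gene == "mid"])
  expect_lt(abs(rr - 4.09) / 4.09, 0.35)
})
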