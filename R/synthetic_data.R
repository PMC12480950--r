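# Seeded generators emulating the field survey and laboratory designs, so
# every analysis stage can be exercised against known ground truth. Each
# generator is a pure function of its config + seed, and each has an exact
# noise-free inversion by its paired analysis stage.

.rtruncnorm01 <- function(n, mean, sd) {
  # truncated normal on (0, 1]
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0 && v <= 1) break
    }
    out[i] <- v
  }
  out
}

# Noise sd producing (in expectation) coupling R^2 = r2 for a linear signal
# with realized variance var_sig.
.noise_for_r2 <- function(var_sig, r2) {
  if (r2 <= 0 || r2 > 1) stop("R^2 target must lie in (0, 1]", call. = FALSE)
  if (r2 == 1) return(0)
  if (var_sig <= 0) {
    stop("infeasible coupling: zero signal variance with R^2 target < 1",
         call. = FALSE)
  }
  sqrt(var_sig * (1 - r2) / r2)
}

#' Survey generator configuration
#'
#' Defaults emulate the 12-site field survey: humic substances (HS) spanning
#' 9.5-230.1 mg g^-1 sediment (log-uniform; field HS spans an order of
#' magnitude), humic acid 92.8 +/- 9.4 % of HS, maximum power density (MPD)
#' linearly coupled to HS at R^2 ~ 0.74, excess N2 driven by MPD at
#' R^2 ~ 0.79, N2O metrics negatively coupled to MPD, and independent
#' water/sediment physicochemistry.
#'
#' @param n_sites number of sites
#' @param hs_range HS range (mg g^-1 sediment)
#' @param ha_fraction_mean,ha_fraction_sd HA share of HS, truncated to (0, 1]
#' @param mpd_hs_slope MPD per unit HS (uW m^-2 per mg g^-1)
#' @param mpd_hs_r2 target HS-MPD coupling R^2 (1 = noise-free)
#' @param n2_mpd_slope excess-N2 per unit MPD (umol L^-1 per uW m^-2)
#' @param n2_mpd_r2 target MPD-excess-N2 coupling R^2
#' @param n2o_mpd_slope negative N2O-MPD coupling (umol L^-1 per uW m^-2)
#' @param seed mandatory RNG seed
#' @return list of class `survey_config`
#' @export
survey_config <- function(n_sites = 12, hs_range = c(9.5, 230.1),
                          ha_fraction_mean = 0.928, ha_fraction_sd = 0.094,
                          mpd_hs_slope = 0.33, mpd_hs_r2 = 0.7355,
                          n2_mpd_slope = 0.35, n2_mpd_r2 = 0.7926,
                          n2o_mpd_slope = -5e-4, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_sites >= 3, all(hs_range > 0), hs_range[2] > hs_range[1])
  structure(list(n_sites = n_sites, hs_range = hs_range,
                 ha_fraction_mean = ha_fraction_mean,
                 ha_fraction_sd = ha_fraction_sd,
                 mpd_hs_slope = mpd_hs_slope, mpd_hs_r2 = mpd_hs_r2,
                 n2_mpd_slope = n2_mpd_slope, n2_mpd_r2 = n2_mpd_r2,
                 n2o_mpd_slope = n2o_mpd_slope, seed = seed),
            class = "survey_config")
}

#' Generate a synthetic site survey
#'
#' Draws a per-site table with the statistical structure the driver analysis
#' assumes: only MPD drives excess N2 (all physicochemistry columns are
#' independent noise), MPD is driven by HS, and N2O metrics decline with
#' MPD. Noise standard deviations are calibrated against the realized signal
#' variance so the empirical couplings land near the configured R^2 targets.
#'
#' @param config a [survey_config()]
#' @return data.frame with one row per site and attribute `truth` recording
#'   the generating slopes and noise sds
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)
  n <- config$n_sites
  hs <- exp(stats::runif(n, log(config$hs_range[1]), log(config$hs_range[2])))
  ha_frac <- .rtruncnorm01(n, config$ha_fraction_mean, config$ha_fraction_sd)
  ha <- hs * ha_frac
  fa <- hs * (1 - ha_frac)

  mpd_sig <- config$mpd_hs_slope * hs
  mpd_sd <- .noise_for_r2(stats::var(mpd_sig), config$mpd_hs_r2)
  mpd <- mpd_sig + stats::rnorm(n, 0, mpd_sd)

  dn2_sig <- config$n2_mpd_slope * mpd
  dn2_sd <- .noise_for_r2(stats::var(dn2_sig), config$n2_mpd_r2)
  delta_n2 <- dn2_sig + stats::rnorm(n, 0, dn2_sd)

  temp_c <- stats::rnorm(n, 18, 2)
  n2_eq <- equilibrium_concentration("N2", temp_c + 273.15, 0)
  n2_dissolved <- n2_eq + delta_n2

  delta_n2o <- 0.05 + config$n2o_mpd_slope * mpd + stats::rnorm(n, 0, 0.008)
  n2o_ratio <- delta_n2o / (abs(delta_n2o) + pmax(delta_n2, 1e-6))

  tbl <- data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    hs = hs, ha = ha, fa = fa, ha_fraction = ha_frac, mpd = mpd,
    n2_dissolved = n2_dissolved, delta_n2 = delta_n2,
    delta_n2o = delta_n2o, n2o_ratio = n2o_ratio,
    do_mg_l = stats::rnorm(n, 8, 1.5), ph = stats::rnorm(n, 8, 0.4),
    temp_c = temp_c,
    no3 = stats::rlnorm(n, log(1.5), 0.5),
    nh4 = stats::rlnorm(n, log(2.0), 0.5),
    no2 = stats::rlnorm(n, log(0.1), 0.5))
  attr(tbl, "truth") <- list(mpd_hs_slope = config$mpd_hs_slope,
                             mpd_noise_sd = mpd_sd,
                             n2_mpd_slope = config$n2_mpd_slope,
                             dn2_noise_sd = dn2_sd)
  tbl
}

#' Incubation generator configuration
#'
#' Defaults emulate the paired Blank/HS_C sacrificial-vial design: 12 mL
#' vials with ~2 g sediment and 11 mL of 15NO3- solution, time points
#' 0/6/12/24 h, three replicate vials per time point, and HS addition
#' multiplying the denitrification rate by 2.6. Default base rates give a
#' denitrification share of N2 production near 71%.
#'
#' @param d_rate,a_rate true denitrification and anammox N2 production rates
#'   (umol L^-1 h^-1)
#' @param fn 15N atom fraction of the nitrate pool
#' @param timepoints sampling times (h)
#' @param replicates vials per time point
#' @param noise_sd Gaussian measurement noise on concentrations (umol L^-1)
#' @param hs_effect multiplier applied to d_rate in HS_C vials
#' @param n_pairs number of Blank/HS_C pairs (biological replicates)
#' @param pair_cv lognormal coefficient of variation of per-pair baseline
#'   rates (biological heterogeneity)
#' @param native_hs optional per-pair native HS (mg g^-1); when supplied, the
#'   realized HS_C enhancement decays exponentially with native HS toward 1
#' @param hs_decay decay constant of the enhancement vs native HS (per
#'   mg g^-1)
#' @param seed mandatory RNG seed
#' @return list of class `incubation_config`
#' @export
incubation_config <- function(d_rate = 0.05, a_rate = 0.02, fn = 0.8,
                              timepoints = c(0, 6, 12, 24), replicates = 3,
                              noise_sd = 0.02, hs_effect = 2.6, n_pairs = 8,
                              pair_cv = 0.2, native_hs = NULL,
                              hs_decay = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(d_rate >= 0, a_rate >= 0, fn > 0, fn <= 1, replicates >= 1,
            length(timepoints) >= 2)
  if (!is.null(native_hs)) stopifnot(length(native_hs) == n_pairs)
  structure(list(d_rate = d_rate, a_rate = a_rate, fn = fn,
                 timepoints = timepoints, replicates = replicates,
                 noise_sd = noise_sd, hs_effect = hs_effect,
                 n_pairs = n_pairs, pair_cv = pair_cv,
                 native_hs = native_hs, hs_decay = hs_decay, seed = seed),
            class = "incubation_config")
}

# Forward isotope-pairing model: slopes of the two isotopologues implied by
# (D, A, FN). Inverted exactly by ipt_partition().
.ipt_forward_slopes <- function(d, a, fn) {
  c(p29 = 2 * d * fn * (1 - fn) + a * fn, p30 = d * fn^2)
}

#' Generate paired Blank/HS_C labeled incubations
#'
#' Forward isotope-pairing model (29N2 slope = 2 D FN (1-FN) + A FN, 30N2
#' slope = D FN^2), linear in time, with Gaussian measurement noise.
#'
#' @param config an [incubation_config()]
#' @return list of [labeled_incubation()] objects (two per pair), with
#'   attribute `truth` holding the per-pair generating rates
#' @export
generate_incubation <- function(config) {
  stopifnot(inherits(config, "incubation_config"))
  set.seed(config$seed)
  times <- rep(config$timepoints, each = config$replicates)
  out <- list()
  truth <- list()
  for (p in seq_len(config$n_pairs)) {
    base_d <- config$d_rate *
      exp(stats::rnorm(1, 0, config$pair_cv) - config$pair_cv^2 / 2)
    base_a <- config$a_rate *
      exp(stats::rnorm(1, 0, config$pair_cv) - config$pair_cv^2 / 2)
    eff <- if (is.null(config$native_hs)) config$hs_effect
           else 1 + (config$hs_effect - 1) *
             exp(-config$hs_decay * config$native_hs[p])
    for (grp in c("Blank", "HS_C")) {
      d <- if (grp == "HS_C") base_d * eff else base_d
      sl <- .ipt_forward_slopes(d, base_a, config$fn)
      c29 <- pmax(sl["p29"] * times +
                    stats::rnorm(length(times), 0, config$noise_sd), 0)
      c30 <- pmax(sl["p30"] * times +
                    stats::rnorm(length(times), 0, config$noise_sd), 0)
      key <- paste0("pair", p, "_", grp)
      out[[key]] <- labeled_incubation(times, c29, c30, config$fn,
                                       group_label = grp,
                                       pair_id = paste0("pair", p))
      truth[[key]] <- list(d_rate = d, a_rate = base_a, effect = eff)
    }
  }
  attr(out, "truth") <- truth
  out
}

#' Generate headspace-equilibration samples
#'
#' Forward mass balance: the true dissolved concentration partitions between
#' water and headspace (Cg = (Cw0 + Cair Vg/Vl) / (Vg/Vl + K0 R T)), then
#' Gaussian measurement noise is added to the headspace reading. Zero-noise
#' samples are inverted exactly by [headspace_original_concentration()].
#'
#' @param n number of samples
#' @param true_cw true dissolved concentration (umol L^-1)
#' @param cair ambient-air concentration (umol L^-1)
#' @param gas_volume,liquid_volume vial geometry (mL)
#' @param temperature equilibration temperature (K)
#' @param solubility_coeff K0 (mol L^-1 atm^-1); default from
#'   [n2o_solubility_coefficient()] at `temperature`
#' @param noise_sd Gaussian noise on the headspace concentration
#' @param seed mandatory RNG seed
#' @return a [headspace_sample()] (vectorized over `n`) with attribute
#'   `truth` = `true_cw`
#' @export
generate_headspace <- function(n, true_cw, cair = 0.0135, gas_volume = 40,
                               liquid_volume = 160, temperature = 298.15,
                               solubility_coeff = NULL, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  if (is.null(solubility_coeff)) {
    solubility_coeff <- n2o_solubility_coefficient(temperature)
  }
  ratio <- gas_volume / liquid_volume
  k0rt <- solubility_coeff * GAS_CONSTANT_L_ATM * temperature
  cg <- (true_cw + cair * ratio) / (ratio + k0rt)
  cg_obs <- pmax(rep(cg, length.out = n) + stats::rnorm(n, 0, noise_sd), 0)
  s <- headspace_sample(cg_obs, rep(cair, n), gas_volume, liquid_volume,
                        temperature, solubility_coeff)
  attr(s, "truth") <- rep(true_cw, length.out = n)
  s
}

#' Generate a Thevenin-model polarization sweep
#'
#' Forward model V = Voc R / (R + Rint) over a resistance grid, with
#' Gaussian voltage noise. When the grid contains R = Rint the noise-free
#' maximum power density equals the closed form Voc^2 / (4 Rint area).
#'
#' @param voc open-circuit voltage (V)
#' @param rint internal resistance (ohm)
#' @param r_grid external resistance grid (ohm)
#' @param area anode area (m^2)
#' @param noise_sd Gaussian voltage noise (V)
#' @param seed mandatory RNG seed
#' @param sample_id identifier
#' @return a [polarization_sweep()] with attribute `truth`
#' @export
generate_polarization <- function(voc, rint, r_grid, area = 0.01,
                                  noise_sd = 0, seed, sample_id = "sim") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  stopifnot(voc >= 0, rint > 0, all(r_grid > 0))
  v <- voc * r_grid / (r_grid + rint)
  v <- pmax(v + stats::rnorm(length(r_grid), 0, noise_sd), 0)
  s <- polarization_sweep(r_grid, v, area, sample_id)
  attr(s, "truth") <- list(voc = voc, rint = rint,
                           mpd_closed_form = voc^2 / (4 * rint * area) * 1e6)
  s
}

#' Generate a paired qPCR Ct table
#'
#' Reference (16S) Ct values vary around a baseline; Blank target Ct sits a
#' gene-specific offset above the reference; HS_C target Ct is shifted down
#' by log2(fold), so the expression stage recovers the configured
#' fold-ratios. All Ct readings get Gaussian noise.
#'
#' @param true_folds named vector of true HS_C/Blank fold changes per gene
#' @param n_pairs matched Blank/HS_C pairs
#' @param ct_noise_sd Gaussian Ct noise (cycles)
#' @param ref_ct mean 16S reference Ct
#' @param seed mandatory RNG seed
#' @return data.frame in the layout expected by [qpcr_gene_table()], with
#'   attribute `truth` = `true_folds`
#' @export
generate_qpcr <- function(true_folds = c(nirS = 4.6, nirK = 12.0,
                                         nosZI = 7.7, nosZII = 31.5,
                                         omcB = 31.5, omcS = 2.0, pilA = 3.3),
                          n_pairs = 8, ct_noise_sd = 0.25, ref_ct = 15,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  stopifnot(!is.null(names(true_folds)), all(true_folds > 0))
  rows <- list()
  for (g in names(true_folds)) {
    base_offset <- stats::runif(1, 6, 10)  # gene-specific baseline delta-Ct
    for (p in seq_len(n_pairs)) {
      pair_offset <- base_offset + stats::rnorm(1, 0, 0.5)
      ref_b <- ref_ct + stats::rnorm(1, 0, 0.3)
      ref_t <- ref_ct + stats::rnorm(1, 0, 0.3)
      ct_blank <- ref_b + pair_offset + stats::rnorm(1, 0, ct_noise_sd)
      ct_hsc <- ref_t + pair_offset - log2(true_folds[[g]]) +
        stats::rnorm(1, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        target_gene = g,
        ct_target = c(ct_blank, ct_hsc),
        ct_reference = c(ref_b, ref_t),
        group = c("Blank", "HS_C"),
        pair_id = paste0("pair", p), timepoint = 24)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- true_folds
  out
}
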