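# Dissolved-gas chemistry: solubility fits, headspace-equilibrium inversion,
# excess-gas computation, N2:Ar dissolved-N2 estimation and diffusive flux.

#' Ideal gas constant used in the headspace mass balance
#'
#' L atm mol^-1 K^-1, the value conventional in limnological headspace
#' calculations.
#' @export
GAS_CONSTANT_L_ATM <- 0.082

#' Default atmospheric mole fractions (dry air)
#'
#' Configuration values, not hard-wired constants: every function taking a
#' mole fraction accepts an explicit value. N2O is the modern tropospheric
#' level (~332 ppb).
#' @export
atm_mole_fractions <- list(N2 = 0.780840, Ar = 0.009340, N2O = 332e-9)

# Hamme & Emerson (2004) air-saturation fit coefficients, umol kg-1,
# moist atmosphere at 1 atm total pressure.
.he_coef <- list(
  N2 = c(A0 = 6.42931, A1 = 2.92704, A2 = 4.32531, A3 = 4.69149,
         B0 = -7.44129e-3, B1 = -8.02566e-3, B2 = -1.46775e-2),
  Ar = c(A0 = 2.79150, A1 = 3.17609, A2 = 4.13116, A3 = 4.90379,
         B0 = -6.96233e-3, B1 = -7.66670e-3, B2 = -1.16888e-2)
)

.check_ts <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(temperature < 270) ||
      any(temperature > 330)) {
    stop("temperature must lie in [270, 330] K (fit range of the solubility ",
         "parameterizations)", call. = FALSE)
  }
  if (any(!is.finite(salinity)) || any(salinity < 0)) {
    stop("salinity must be >= 0 (practical salinity)", call. = FALSE)
  }
  invisible(TRUE)
}

#' N2O solubility coefficient K0
#'
#' Weiss & Price (1980) ln-polynomial for the N2O solubility (Bunsen-type
#' Henry) coefficient K0 in mol L^-1 atm^-1, as used in the headspace
#' mass-balance inversion.
#'
#' @param temperature absolute temperature (K), valid 270-330 K
#' @param salinity practical salinity, >= 0 (0 for freshwater lakes)
#' @return K0 in mol L^-1 atm^-1
#' @examples
#' n2o_solubility_coefficient(298.15, 0) # ~0.0248
#' @export
n2o_solubility_coefficient <- function(temperature, salinity = 0) {
  .check_ts(temperature, salinity)
  t100 <- temperature / 100
  exp(-62.7062 + 97.3066 / t100 + 24.1406 * log(t100) +
        salinity * (-0.058420 + 0.033193 * t100 - 0.0051313 * t100^2))
}

# Weiss & Price (1980) moist-air equilibrium function F' (mol L-1 atm-1):
# multiplying by the dry-air mole fraction and total pressure gives the
# air-equilibrium dissolved concentration including the water-vapor term.
.n2o_fprime <- function(temperature, salinity) {
  t100 <- temperature / 100
  exp(-165.8806 + 222.8743 / t100 + 92.0792 * log(t100) - 1.48425 * t100^2 +
        salinity * (-0.056235 + 0.031619 * t100 - 0.0048472 * t100^2))
}

.he_saturation <- function(gas, temperature, salinity) {
  a <- .he_coef[[gas]]
  tC <- temperature - 273.15
  ts <- log((298.15 - tC) / (273.15 + tC))
  unname(exp(a["A0"] + a["A1"] * ts + a["A2"] * ts^2 + a["A3"] * ts^3 +
               salinity * (a["B0"] + a["B1"] * ts + a["B2"] * ts^2)))
}

#' Atmospheric-equilibrium dissolved gas concentration
#'
#' Equilibrium ("saturation") concentration of N2, Ar or N2O in water in
#' contact with the atmosphere. N2 and Ar use the Hamme & Emerson (2004)
#' moist-air saturation fits (umol kg^-1, taken as umol L^-1 for fresh
#' water); N2O uses the Weiss & Price (1980) moist-air equilibrium function.
#' The result is rescaled linearly from the fits' reference mole fractions,
#' so halving `atm_mole_fraction` halves the output.
#'
#' @param gas one of "N2", "Ar", "N2O"
#' @param temperature in-situ absolute temperature (K)
#' @param salinity practical salinity
#' @param atm_mole_fraction dry-air mole fraction of the gas, in (0, 1];
#'   defaults to [atm_mole_fractions]
#' @param pressure total atmospheric pressure (atm)
#' @return equilibrium concentration, umol L^-1
#' @examples
#' equilibrium_concentration("Ar", 298.15) # ~12.7 umol/L
#' @export
equilibrium_concentration <- function(gas, temperature, salinity = 0,
                                      atm_mole_fraction = NULL,
                                      pressure = 1) {
  supported <- c("N2", "Ar", "N2O")
  if (!is.character(gas) || length(gas) != 1L || !gas %in% supported) {
    stop("unsupported gas '", paste(gas, collapse = ","),
         "'; supported gases: ", paste(supported, collapse = ", "),
         call. = FALSE)
  }
  .check_ts(temperature, salinity)
  if (is.null(atm_mole_fraction)) atm_mole_fraction <- atm_mole_fractions[[gas]]
  if (!is.finite(atm_mole_fraction) || atm_mole_fraction <= 0 ||
      atm_mole_fraction > 1) {
    stop("atm_mole_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(pressure) || pressure <= 0) {
    stop("pressure must be > 0 atm", call. = FALSE)
  }
  if (gas == "N2O") {
    # mol L-1 atm-1 * (mole fraction) * atm -> mol L-1; to umol L-1
    .n2o_fprime(temperature, salinity) * atm_mole_fraction * pressure * 1e6
  } else {
    .he_saturation(gas, temperature, salinity) *
      (atm_mole_fraction / atm_mole_fractions[[gas]]) * pressure
  }
}

#' Construct a headspace-equilibration sample
#'
#' One equilibrated water/gas pair from the syringe headspace method: a
#' water sample of volume `liquid_volume` shaken against `gas_volume` of
#' ambient air at temperature `temperature`, after which the headspace gas
#' concentration `headspace_conc` is measured.
#'
#' @param headspace_conc gas concentration in the headspace after
#'   equilibration (umol L^-1)
#' @param air_conc ambient-air gas concentration (umol L^-1)
#' @param gas_volume headspace volume (mL)
#' @param liquid_volume water volume (mL)
#' @param temperature absolute temperature during equilibration (K)
#' @param solubility_coeff K0, mol L^-1 atm^-1 (e.g. from
#'   [n2o_solubility_coefficient()])
#' @return object of class `headspace_sample`
#' @export
headspace_sample <- function(headspace_conc, air_conc, gas_volume,
                             liquid_volume, temperature, solubility_coeff) {
  stopifnot(length(headspace_conc) == length(air_conc))
  if (any(gas_volume <= 0) || any(liquid_volume <= 0)) {
    stop("gas_volume and liquid_volume must be > 0 mL", call. = FALSE)
  }
  if (any(temperature < 270) || any(temperature > 330)) {
    stop("equilibration temperature must lie in [270, 330] K", call. = FALSE)
  }
  if (any(solubility_coeff <= 0)) stop("solubility_coeff must be > 0",
                                       call. = FALSE)
  if (any(headspace_conc < 0) || any(air_conc < 0)) {
    stop("gas concentrations must be >= 0", call. = FALSE)
  }
  structure(list(headspace_conc = headspace_conc, air_conc = air_conc,
                 gas_volume = gas_volume, liquid_volume = liquid_volume,
                 temperature = temperature,
                 solubility_coeff = solubility_coeff),
            class = "headspace_sample")
}

#' Recover the original dissolved concentration from a headspace sample
#'
#' Inverts the headspace mass balance
#' \deqn{C_w = C_g (K_0 R T + V_g/V_l) - C_{air} V_g/V_l}
#' where R = 0.082 L atm mol^-1 K^-1. The recovered concentration may be
#' below the air-equilibrium value (undersaturated water); a negative
#' recovery beyond `tolerance` is flagged, never clamped, so mass-balance
#' inconsistencies stay auditable.
#'
#' @param sample a [headspace_sample()]
#' @param tolerance negative recoveries smaller in magnitude than this are
#'   treated as numerically zero-adjacent and not flagged
#' @return data.frame with `cw` (umol L^-1) and logical `flag_negative`
#' @export
headspace_original_concentration <- function(sample, tolerance = 1e-9) {
  stopifnot(inherits(sample, "headspace_sample"))
  ratio <- sample$gas_volume / sample$liquid_volume
  k0rt <- sample$solubility_coeff * GAS_CONSTANT_L_ATM * sample$temperature
  cw <- sample$headspace_conc * (k0rt + ratio) - sample$air_conc * ratio
  flag <- cw < -abs(tolerance)
  if (any(flag)) {
    warning("recovered dissolved concentration negative beyond tolerance ",
            "for ", sum(flag), " sample(s); inputs may be inconsistent",
            call. = FALSE)
  }
  data.frame(cw = cw, flag_negative = flag)
}

#' Excess dissolved gas
#'
#' Difference between the measured dissolved concentration and the
#' atmospheric-equilibrium concentration. Negative values mean
#' undersaturation and are preserved.
#'
#' @param measured measured dissolved concentration (umol L^-1)
#' @param equilibrium atmospheric-equilibrium concentration (umol L^-1)
#' @return excess concentration (umol L^-1)
#' @export
excess_gas <- function(measured, equilibrium) {
  if (any(!is.finite(measured)) || any(!is.finite(equilibrium))) {
    stop("measured and equilibrium concentrations must be finite",
         call. = FALSE)
  }
  measured - equilibrium
}

#' Dissolved N2 from a measured N2:Ar ratio
#'
#' The N2:Ar method: argon is biologically inert, so the in-situ dissolved Ar
#' concentration is taken as its atmospheric-equilibrium value and the
#' measured N2:Ar ratio scales it to dissolved N2.
#'
#' @param n2ar_ratio measured dissolved N2:Ar concentration ratio (> 0)
#' @param temperature in-situ absolute temperature (K)
#' @param salinity practical salinity
#' @param ar_mole_fraction atmospheric Ar mole fraction
#' @param pressure atm
#' @return dissolved N2 (umol L^-1)
#' @export
n2_from_n2ar <- function(n2ar_ratio, temperature, salinity = 0,
                         ar_mole_fraction = atm_mole_fractions$Ar,
                         pressure = 1) {
  if (any(n2ar_ratio <= 0)) stop("n2ar_ratio must be > 0", call. = FALSE)
  n2ar_ratio * equilibrium_concentration("Ar", temperature, salinity,
                                         ar_mole_fraction, pressure)
}

#' Diffusive air-water gas flux
#'
#' F = k * excess concentration, with the excess converted from umol L^-1 to
#' umol m^-3 (factor 1000) so that k in m d^-1 yields umol m^-2 d^-1.
#' Negative excess gives a negative flux (influx from the atmosphere).
#'
#' @param k gas transfer (piston) velocity, m d^-1, >= 0
#' @param delta excess dissolved gas (umol L^-1)
#' @return flux (umol m^-2 d^-1)
#' @export
diffusive_flux <- function(k, delta) {
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("gas transfer velocity k must be >= 0", call. = FALSE)
  }
  k * delta * 1000
}

# Wanninkhof (2014) Schmidt number polynomial for N2O in fresh water.
.schmidt_n2o_fresh <- function(tC) {
  2141.2 - 152.56 * tC + 5.8963 * tC^2 - 0.12411 * tC^3 + 0.0010655 * tC^4
}

#' Wind-based gas transfer velocity (optional helper)
#'
#' Quadratic wind-speed law k600 = 0.251 u10^2 (cm h^-1) with Schmidt-number
#' scaling (Sc/600)^-0.5 for N2O in fresh water, returned in m d^-1. The
#' piston velocity is otherwise user-supplied data; this helper exists so a
#' complete flux chain can be run when only wind speed is available.
#'
#' @param wind_u10 wind speed at 10 m (m s^-1), >= 0
#' @param temperature water temperature (K)
#' @return k (m d^-1)
#' @export
gas_transfer_velocity <- function(wind_u10, temperature = 298.15) {
  if (any(wind_u10 < 0)) stop("wind speed must be >= 0", call. = FALSE)
  tC <- temperature - 273.15
  k600_cm_h <- 0.251 * wind_u10^2
  k600_cm_h * (.schmidt_n2o_fresh(tC) / 600)^(-0.5) * 0.24
}

#' Assemble a dissolved-gas profile for one site
#'
#' Convenience wrapper combining measured and equilibrium concentrations into
#' the per-site gas summary used by the driver analysis: excess N2 and N2O
#' and the diffusive N2O flux.
#'
#' @param site_id identifier
#' @param n2_measured,n2o_measured dissolved concentrations (umol L^-1)
#' @param temperature in-situ absolute temperature (K)
#' @param salinity practical salinity
#' @param k gas transfer velocity (m d^-1)
#' @param pressure atm
#' @return one-row data.frame with measured, equilibrium, excess and flux
#'   columns
#' @export
dissolved_gas_profile <- function(site_id, n2_measured, n2o_measured,
                                  temperature, salinity = 0, k = 0,
                                  pressure = 1) {
  n2_eq <- equilibrium_concentration("N2", temperature, salinity,
                                     pressure = pressure)
  n2o_eq <- equilibrium_concentration("N2O", temperature, salinity,
                                      pressure = pressure)
  d_n2 <- excess_gas(n2_measured, n2_eq)
  d_n2o <- excess_gas(n2o_measured, n2o_eq)
  data.frame(site_id = site_id, n2_measured = n2_measured,
             n2_equilibrium = n2_eq, n2o_measured = n2o_measured,
             n2o_equilibrium = n2o_eq, delta_n2 = d_n2, delta_n2o = d_n2o,
             k = k, flux_n2o = diffusive_flux(k, d_n2o))
}
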