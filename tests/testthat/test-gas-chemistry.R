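test_that("N2O solubility coefficient matches the published polynomial", {
  # frozen oracle values (standalone evaluation of the coefficient polynomial)
  expect_equal(n2o_solubility_coefficient(298.15, 0), 0.02478356469,
               tolerance = 1e-8)
  expect_equal(n2o_solubility_coefficient(278.15, 0), 0.04845590686,
               tolerance = 1e-8)
  expect_equal(n2o_solubility_coefficient(298.15, 35), 0.02075458914,
               tolerance = 1e-8)
  for (TK in seq(274, 328, by = 6)) {
    for (S in c(0, 5, 35)) {
      expect_equal(n2o_solubility_coefficient(TK, S), oracle_wp_k0(TK, S),
                   tolerance = 1e-6)
    }
  }
})

test_that("solubility falls with warming and with salt", {
  expect_gt(n2o_solubility_coefficient(278.15, 0),
            n2o_solubility_coefficient(298.15, 0))
  expect_gt(n2o_solubility_coefficient(298.15, 0),
            n2o_solubility_coefficient(298.15, 35))
  k <- n2o_solubility_coefficient(seq(272, 328, by = 2), 0)
  expect_true(all(diff(k) < 0))
})

test_that("out-of-range temperature or salinity raises a domain error", {
  expect_error(n2o_solubility_coefficient(250, 0), "270")
  expect_error(n2o_solubility_coefficient(340, 0), "330")
  expect_error(n2o_solubility_coefficient(298.15, -1), "salinity")
  expect_error(equilibrium_concentration("N2", 250), "270")
})

test_that("equilibrium concentrations match the saturation-fit oracles", {
  # frozen: Hamme-Emerson N2 and Ar at 25 C, S = 0 (umol/kg ~ umol/L)
  expect_equal(equilibrium_concentration("N2", 298.15, 0), 494.2267829,
               tolerance = 1e-7)
  expect_equal(equilibrium_concentration("Ar", 298.15, 0), 12.70178016,
               tolerance = 1e-7)
  for (TK in c(277.15, 288.15, 298.15)) {
    for (S in c(0, 35)) {
      expect_equal(equilibrium_concentration("N2", TK, S),
                   oracle_he(TK, S, "N2"), tolerance = 1e-6)
      expect_equal(equilibrium_concentration("Ar", TK, S),
                   oracle_he(TK, S, "Ar"), tolerance = 1e-6)
      expect_equal(equilibrium_concentration("N2O", TK, S),
                   oracle_wp_fprime(TK, S) * 332e-9 * 1e6, tolerance = 1e-6)
    }
  }
})

test_that("equilibrium concentration is linear in mole fraction and pressure", {
  base <- equilibrium_concentration("N2", 298.15, 0, atm_mole_fraction = 0.39)
  expect_equal(equilibrium_concentration("N2", 298.15, 0,
                                         atm_mole_fraction = 0.78),
               2 * base, tolerance = 1e-12)
  expect_equal(equilibrium_concentration("N2O", 298.15, 0, pressure = 0.5),
               0.5 * equilibrium_concentration("N2O", 298.15, 0),
               tolerance = 1e-12)
  expect_error(equilibrium_concentration("CH4", 298.15), "supported gases")
})

test_that("headspace inversion recovers equilibrium water as a fixed point", {
  # Cg = Cair leaves the headspace unchanged: water was at air equilibrium
  k0 <- n2o_solubility_coefficient(298.15)
  s <- headspace_sample(headspace_conc = 0.0135, air_conc = 0.0135,
                        gas_volume = 40, liquid_volume = 160,
                        temperature = 298.15, solubility_coeff = k0)
  out <- headspace_original_concentration(s)
  expect_equal(out$cw, 0.0135 * k0 * GAS_CONSTANT_L_ATM * 298.15,
               tolerance = 1e-12)
  expect_false(out$flag_negative)
})

test_that("headspace round trip inverts the forward mass balance exactly", {
  # field geometry: 40 mL air replacing 40 mL of a 200 mL water sample
  ratio <- 40 / 160
  k0rt <- 0.586 / (GAS_CONSTANT_L_ATM * 298.15) * GAS_CONSTANT_L_ATM * 298.15
  cg <- oracle_forward_headspace(0.0200, 0.0135, ratio, 0.586)
  s <- headspace_sample(cg, 0.0135, 40, 160, 298.15,
                        0.586 / (GAS_CONSTANT_L_ATM * 298.15))
  expect_equal(headspace_original_concentration(s)$cw, 0.0200,
               tolerance = 1e-12)
})

test_that("inconsistent headspace inputs flag a negative recovery", {
  k0 <- n2o_solubility_coefficient(298.15)
  s <- headspace_sample(headspace_conc = 0.001, air_conc = 0.05,
                        gas_volume = 40, liquid_volume = 160,
                        temperature = 298.15, solubility_coeff = k0)
  expect_warning(out <- headspace_original_concentration(s), "negative")
  expect_true(out$flag_negative)
  expect_lt(out$cw, 0)  # reported raw, not clamped
})

test_that("excess gas is a signed difference", {
  expect_equal(excess_gas(500, 500), 0)
  expect_equal(excess_gas(500, 480), 20)
  expect_equal(excess_gas(0.010, 0.0135), -0.0035)
  expect_error(excess_gas(NA, 1), "finite")
})

test_that("N2:Ar method is self-consistent and linear", {
  n2eq <- equilibrium_concentration("N2", 288.15, 0)
  areq <- equilibrium_concentration("Ar", 288.15, 0)
  expect_equal(n2_from_n2ar(n2eq / areq, 288.15, 0), n2eq, tolerance = 1e-10)
  expect_equal(n2_from_n2ar(80, 288.15, 0), 2 * n2_from_n2ar(40, 288.15, 0),
               tolerance = 1e-12)
  expect_equal(n2_from_n2ar(40, 298.15, 0),
               40 * oracle_he(298.15, 0, "Ar"), tolerance = 1e-6)
})

test_that("diffusive flux converts umol/L excess to areal units and keeps sign", {
  expect_equal(diffusive_flux(0.7, 0), 0)
  expect_equal(diffusive_flux(0.5, 2.0), 1000)   # 2 umol/L = 2000 umol/m^3
  expect_equal(diffusive_flux(1.0, -0.004), -4.0)
  expect_equal(diffusive_flux(2 * 0.5, 2.0), 2 * diffusive_flux(0.5, 2.0))
  expect_error(diffusive_flux(-0.1, 1), ">= 0")
})

test_that("wind-based transfer velocity follows the quadratic law", {
  expect_equal(gas_transfer_velocity(0), 0)
  expect_equal(gas_transfer_velocity(10), 4 * gas_transfer_velocity(5),
               tolerance = 1e-12)
  # frozen oracle: k600 = 0.251 u^2 cm/h, (Sc/600)^-0.5, N2O fresh at 25 C
  expect_equal(gas_transfer_velocity(5, 298.15), 1.66754525,
               tolerance = 1e-7)
  u <- seq(0, 12, by = 0.5)
  expect_true(all(diff(gas_transfer_velocity(u)) >= 0))
})

test_that("site gas profile wires excess and flux together", {
  pr <- dissolved_gas_profile("S01", n2_measured = 520, n2o_measured = 0.02,
                              temperature = 291.15, k = 0.8)
  expect_equal(pr$delta_n2, pr$n2_measured - pr$n2_equilibrium)
  expect_equal(pr$flux_n2o, 0.8 * pr$delta_n2o * 1000)
})
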