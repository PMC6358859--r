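# Formulation-level computations: drug load, TGA deconvolution, wetting,
# saturation.

test_that("drug load follows the mass-ratio definition and its monotonicity", {
  expect_equal(drug_load(0.6, 1.0), 0.375)
  expect_equal(drug_load(0, 1), 0)
  expect_equal(drug_load(0.3, 0.3), 0.5)
  expect_error(drug_load(0, 0), "zero")
  m <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(drug_load(m, 1)) > 0))
  expect_true(all(diff(drug_load(1, m)) < 0))
})

test_that("reference mass-loss fractions are simple ratios with feasibility checks", {
  expect_equal(tga_reference_fraction(0, 100), 0)
  expect_equal(tga_reference_fraction(100, 100), 1)
  expect_equal(tga_reference_fraction(25, 100), 0.25)
  expect_error(tga_reference_fraction(101, 100), "between")
})

test_that("TGA deconvolution handles the pure-component limits and infeasible losses", {
  refs <- tga_reference_set(f_M = 0.9, f_FCC = 0.05)
  pure_carrier <- tga_content(0.05 * 200, 200, refs)
  expect_equal(pure_carrier$m_M_mg, 0, tolerance = 1e-9)
  expect_equal(pure_carrier$DL_est, 0, tolerance = 1e-9)
  pure_material <- tga_content(0.9 * 200, 200, refs)
  expect_equal(pure_material$m_FCC_mg, 0, tolerance = 1e-9)
  expect_equal(pure_material$DL_est, 1, tolerance = 1e-9)
  expect_error(tga_content(0.95 * 200, 200, refs), "feasible")
  expect_error(tga_content(0.01 * 200, 200, refs), "feasible")
})

test_that("capillary constant calibration inverts a known-constant trace", {
  hex <- liquid_props(654.8, 0.29, 17.9)
  cc <- 2.4e-7
  tr <- simulate_sorption(hex, 0, cc, duration_s = 50)
  expect_lt(abs(calibrate_capillary_constant(tr, hex) - cc) / cc, 1e-9)
  # halving surface tension at a fixed trace doubles ... i.e. c ~ 1/sigma
  hex2 <- liquid_props(654.8, 0.29, 2 * 17.9)
  expect_equal(calibrate_capillary_constant(tr, hex2),
               calibrate_capillary_constant(tr, hex) / 2, tolerance = 1e-12)
  flat <- tibble::tibble(time_s = 0:10, mass_g = rep(0, 11))
  class(flat) <- c("sorption_trace", class(flat))
  expect_error(calibrate_capillary_constant(flat, hex), "no uptake")
})

test_that("contact angles of all six loading solutions round-trip within 0.1 degree", {
  cc <- 2.4e-7
  tab <- loading_solutions()
  for (i in seq_len(nrow(tab))) {
    liq <- liquid_props(tab$density[i], tab$viscosity[i],
                        tab$surface_tension[i])
    tr <- simulate_sorption(liq, tab$contact_angle[i], cc, duration_s = 60)
    expect_lt(abs(washburn_contact_angle(tr, liq, cc) -
                    tab$contact_angle[i]), 0.1)
  }
  # theta = 0 recovers cos(theta) = 1; scaling c and slope together is neutral
  liq <- liquid_props(999.1, 0.69, 50.8)
  tr0 <- simulate_sorption(liq, 0, cc)
  expect_lt(washburn_contact_angle(tr0, liq, cc), 1e-6)
  tr2 <- tr0
  tr2$mass_g <- tr0$mass_g * sqrt(3)
  expect_equal(washburn_contact_angle(tr2, liq, 3 * cc),
               washburn_contact_angle(tr0, liq, cc), tolerance = 1e-9)
  # an over-calibrated constant triggers the data-quality warning
  expect_warning(th <- washburn_contact_angle(tr0, liq, cc / 2), "cos")
  expect_equal(th, 0)
})

test_that("saturation analysis reproduces the solvent-evaporation worked example", {
  bsa_high <- formulation_record(m_M = 0.9, m_FCC = 2.1,
                                 solvent_volume_mL = 20,
                                 solubility_g_per_mL = 0.392,
                                 label = "BSA-high")
  rep <- saturation_analysis(bsa_high, specific_pore_volume = 0.438)
  expect_equal(round(rep$V_sat_mL, 2), 2.30)
  expect_equal(round(rep$fraction_in_pores, 2), 0.40)
  expect_true(rep$external_deposition)
  expect_false(rep$never_fully_dissolved)

  # infinitely soluble material never precipitates externally
  easy <- formulation_record(0.9, 2.1, 20, solubility_g_per_mL = 1e9)
  rep2 <- saturation_analysis(easy, 0.438)
  expect_lt(rep2$V_sat_mL, 1e-8)
  expect_false(rep2$external_deposition)
  expect_error(
    saturation_analysis(formulation_record(1, 1, 10, 0), 0.4), "Solubility"
  )
})
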