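# Young-Laplace conversion, intrusion interpretation, tablet porosity.

test_that("pressure-diameter conversion matches the closed form and inverts exactly", {
  hg <- mercury_params(gamma_mN_m = 485, theta_deg = 130)
  # 4 * 0.485 N/m * cos(50 deg) / 100 nm
  expect_equal(diameter_to_pressure(100, hg), 1.247e7, tolerance = 1e-3)
  expect_equal(pressure_to_diameter(1.247e7, hg), 100, tolerance = 1e-3)
  d <- c(5, 50, 500, 5e3, 3.6e5)
  expect_equal(pressure_to_diameter(diameter_to_pressure(d, hg), hg), d,
               tolerance = 1e-12)
  # doubling pressure halves diameter
  expect_equal(pressure_to_diameter(2e6, hg),
               pressure_to_diameter(1e6, hg) / 2, tolerance = 1e-12)
  expect_error(mercury_params(theta_deg = 60), "non-wetting")
})

test_that("intrusion curves convert to volume-conserving distributions", {
  hg <- mercury_params()
  # single volume step at one pressure -> a single nonzero bin
  p1 <- diameter_to_pressure(80, hg)
  curve <- tibble::tibble(pressure_Pa = c(p1 * 0.5, p1, p1 * 2),
                          cum_vol_mL_per_g = c(0, 0.3, 0.3))
  psd <- intrusion_to_psd(curve, hg)
  expect_equal(sum(psd$spec_vol_mL_per_g > 0), 1L)
  expect_equal(sum(psd$spec_vol_mL_per_g), 0.3, tolerance = 1e-12)

  bad <- tibble::tibble(pressure_Pa = c(1e5, 2e5, 3e5),
                        cum_vol_mL_per_g = c(0.1, 0.05, 0.2))
  expect_error(intrusion_to_psd(bad, hg), "rows 2")
})

test_that("cylindrical pores (throat = body) round-trip through the simulator bin-for-bin", {
  hg <- mercury_params()
  diams <- rep(c(30, 80, 200), times = c(20, 10, 5))
  net <- make_cylinder_network(diams)
  curve <- simulate_intrusion(net, hg)
  psd <- intrusion_to_psd(curve, hg)
  truth <- network_psd(net)
  expect_equal(psd$spec_vol_mL_per_g, truth$spec_vol_mL_per_g,
               tolerance = 1e-9)
})

test_that("the ink bottle registers body volume at the throat diameter", {
  hg <- mercury_params()
  net <- make_ink_bottle(body_nm = 200, throat_nm = 40)
  curve <- simulate_intrusion(net, hg)
  psd <- intrusion_to_psd(curve, hg)
  nz <- which(psd$spec_vol_mL_per_g > 0)
  expect_length(nz, 1L)
  expect_true(psd$bin_lo_nm[nz] <= 40 && psd$bin_hi_nm[nz] >= 40)
  v <- network_volumes(net)
  expect_equal(sum(psd$spec_vol_mL_per_g),
               v$pore_nm3 * 1e-21 / v$sample_mass_g, tolerance = 1e-9)
})

test_that("fully blocked exteriors intrude nothing despite nonzero pore volume", {
  net <- generate_network(network_spec(domain_size_nm = 800, seed = 6))
  sealed <- apply_loading(net, loading_mode("surface_blocking", 1), seed = 1)
  curve <- simulate_intrusion(sealed)
  expect_equal(max(curve$cum_vol_mL_per_g), 0)
  expect_gt(network_volumes(sealed)$pore_nm3, 0)
})

test_that("intruded volume is bounded by the accessible pore volume with equality at full access", {
  net <- generate_network(network_spec(domain_size_nm = 800, seed = 10))
  curve <- simulate_intrusion(net)
  v <- network_volumes(net)
  acc <- accessible_volume_fraction(net) * v$pore_nm3 * 1e-21 / v$sample_mass_g
  expect_lte(max(curve$cum_vol_mL_per_g), acc + 1e-12)
  # schedule reaching below the smallest throat diameter -> equality
  expect_equal(max(curve$cum_vol_mL_per_g), acc, tolerance = 1e-9)
  # apparent average diameter never exceeds the true body average (ink-bottle bias)
  psd <- intrusion_to_psd(simulate_intrusion(net), bin_edges = psd_bin_edges())
  expect_lt(psd_summary(psd)$avg_diameter_volwt_nm,
            mean(net$bodies$diameter_nm))
})

test_that("display smoothing averages plateaus but protects extrema", {
  expect_equal(smooth_for_display(rep(2, 10)), rep(2, 10))
  lin <- as.numeric(1:11)
  expect_equal(smooth_for_display(lin)[3:9], lin[3:9])
  # hand-computed 7-point case: spike at position 4
  x <- c(1, 1, 1, 10, 1, 1, 1)
  sm <- smooth_for_display(x, period = 3)
  expect_equal(sm[4], 10)                      # extremum untouched
  expect_equal(sm[2], 1)                       # flat neighbourhood
  expect_equal(smooth_for_display(c(1, 2), period = 5), c(1, 2))
  expect_error(smooth_for_display(x, period = 4), "odd")
})

test_that("tablet porosity follows the density-ratio identities", {
  t1 <- tablet_porosity(m_T = 1, V_T = 0.8475, rho_S = 2.95)
  expect_equal(t1$P_I, 0.600, tolerance = 1e-3)
  expect_equal(t1$V_P + t1$V_S, t1$V_T, tolerance = 1e-12)
  t2 <- tablet_porosity(m_T = 2.95, V_T = 1, rho_S = 2.95)
  expect_equal(t2$P_I, 0)
  expect_equal(t2$V_P, 0)
  expect_error(tablet_porosity(m_T = 3, V_T = 1, rho_S = 2.95), "exceeds")
})

test_that("averaged skeletal density is the mass-weighted mean", {
  expect_equal(round(averaged_skeletal_density(3.16, 2.73, 0.51), 2), 2.95)
  expect_equal(averaged_skeletal_density(3.16, 2.73, 1), 3.16)
  expect_equal(averaged_skeletal_density(2.5, 2.5, 0.5), 2.5)
})
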