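# Synthetic pore-network generator and loading emulation.

test_that("generated networks hit the target porosity (voxel oracle)", {
  spec <- network_spec(domain_size_nm = 1000, target_porosity = 0.60, seed = 11)
  net <- generate_network(spec)
  expect_true(all(tabulate(c(net$throats$from,
                             net$throats$to[net$throats$to > 0]),
                           nbins = nrow(net$bodies)) >= 1))
  expect_equal(voxel_porosity(net, m = 120), 0.60, tolerance = 0.02 / 0.60)
  # a different porosity level, same oracle
  net2 <- generate_network(network_spec(domain_size_nm = 1000,
                                        target_porosity = 0.35, seed = 11))
  expect_lt(abs(voxel_porosity(net2, m = 120) - 0.35), 0.02)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  spec <- network_spec(domain_size_nm = 800, seed = 4)
  expect_identical(generate_network(spec), generate_network(spec))
  spec2 <- network_spec(domain_size_nm = 800, seed = 5)
  expect_false(identical(generate_network(spec), generate_network(spec2)))
})

test_that("degenerate one-body spec yields one body with exterior access", {
  net <- generate_network(network_spec(n_bodies = 1, target_porosity = 0.05,
                                       domain_size_nm = 500, seed = 2))
  expect_equal(nrow(net$bodies), 1L)
  expect_gte(sum(net$throats$to == 0L), 1L)
  expect_equal(accessible_volume_fraction(net), 1)
})

test_that("infeasible porosity requests error instead of silently truncating", {
  expect_error(
    generate_network(network_spec(target_porosity = 0.95,
                                  domain_size_nm = 600, seed = 1)),
    "infeasible|porosity"
  )
})

test_that("throats never exceed their adjacent bodies and all diameters are positive", {
  net <- generate_network(network_spec(domain_size_nm = 1000, seed = 9))
  th <- net$throats
  internal <- th$to > 0L
  d <- net$bodies$diameter_nm
  expect_true(all(th$diameter_nm[internal] <=
                    pmin(d[th$from[internal]], d[th$to[internal]]) + 1e-9))
  expect_true(all(d > 0))
  expect_true(all(th$diameter_nm > 0))
})

test_that("pore filling conserves skeleton + deposit + pore volume", {
  net <- generate_network(network_spec(domain_size_nm = 1000, seed = 11))
  v0 <- network_volumes(net)
  for (fill in c(0.25, 0.5, 0.75)) {
    loaded <- apply_loading(net, loading_mode("pore_filling", fill))
    v1 <- network_volumes(loaded)
    expect_lt(
      abs(v1$pore_nm3 + v1$deposit_nm3 - v0$pore_nm3) / v0$pore_nm3, 1e-9
    )
    expect_equal(v1$deposit_nm3 / v0$pore_nm3, fill, tolerance = 1e-9)
    expect_equal(v1$skeleton_nm3, v0$skeleton_nm3)
  }
})

test_that("loading at fill 0 is the identity; fill 1 closes every pore", {
  net <- generate_network(network_spec(domain_size_nm = 800, seed = 3))
  expect_identical(apply_loading(net, loading_mode("pore_filling", 0)), net)
  full <- apply_loading(net, loading_mode("pore_filling", 1))
  expect_equal(network_volumes(full)$pore_nm3, 0)
  expect_true(all(full$throats$blocked | full$throats$diameter_nm <= 0))
})

test_that("surface blocking preserves body volume and cuts reachability (BFS oracle)", {
  net <- generate_network(network_spec(domain_size_nm = 1000, seed = 7))
  loaded <- apply_loading(net, loading_mode("surface_blocking", 0.5), seed = 2)
  n0 <- nrow(net$bodies)
  expect_identical(loaded$bodies$diameter_nm[seq_len(n0)],
                   net$bodies$diameter_nm)
  expect_identical(loaded$bodies$deposit_nm[seq_len(n0)],
                   net$bodies$deposit_nm)
  # independent BFS oracle agrees with the packaged graph reachability
  expect_equal(bfs_accessible_fraction(loaded),
               accessible_volume_fraction(loaded), tolerance = 1e-12)
  expect_lte(accessible_volume_fraction(loaded),
             0.5 * accessible_volume_fraction(net) + 1e-12)
  # appended voids are interparticle and above the 500 nm boundary
  voids <- loaded$bodies[loaded$bodies$interparticle, ]
  expect_gt(nrow(voids), 0)
  expect_true(all(voids$diameter_nm >= 500))
})

test_that("network PSD is a specific-volume histogram that sums to the pore volume", {
  net <- generate_network(network_spec(domain_size_nm = 800, seed = 13))
  psd <- network_psd(net)
  v <- network_volumes(net)
  expect_equal(sum(psd$spec_vol_mL_per_g),
               v$pore_nm3 * 1e-21 / v$sample_mass_g, tolerance = 1e-12)
  expect_true(all(psd$spec_vol_mL_per_g >= 0))
})

test_that("fill_fraction outside [0,1] is rejected", {
  expect_error(loading_mode("pore_filling", -0.1), "0,1")
  expect_error(loading_mode("surface_blocking", 1.5), "0,1")
})
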