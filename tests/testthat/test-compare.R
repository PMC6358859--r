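# MIP-vs-image comparison: diameter ratio, volume correlation, pore states.

test_that("body/throat ratio matches the worked numbers", {
  expect_equal(round(body_throat_ratio(108, 23), 1), 4.7)
  expect_equal(body_throat_ratio(50, 50), 1.0)
  expect_equal(body_throat_ratio(100, 25, correct_stereology = TRUE),
               4 / pi * 4, tolerance = 1e-12)
})

test_that("specific-volume correlation equals hand-computed least squares", {
  exact <- tibble::tibble(mip = c(0.1, 0.3, 0.5), image = c(0.05, 0.15, 0.25))
  fit <- correlate_specific_volumes(exact)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # three hand-picked points: closed-form OLS
  x <- c(1, 2, 4); y <- c(1, 3, 4)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2_hand <- (sum((x - mean(x)) * (y - mean(y)))^2 /
                (sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  f2 <- correlate_specific_volumes(tibble::tibble(mip = x, image = y))
  expect_equal(f2$slope, slope_hand, tolerance = 1e-12)
  expect_equal(f2$r_squared, r2_hand, tolerance = 1e-12)

  # excluded outliers do not move the fit; order does not matter
  with_out <- tibble::tibble(mip = c(x, 10), image = c(y, 0),
                             excluded = c(FALSE, FALSE, FALSE, TRUE))
  f3 <- correlate_specific_volumes(with_out)
  expect_equal(f3$slope, f2$slope)
  expect_equal(f3$r_squared, f2$r_squared)
  shuffled <- with_out[c(3, 1, 4, 2), ]
  f4 <- correlate_specific_volumes(shuffled)
  expect_equal(f4$slope, f3$slope)
  expect_error(correlate_specific_volumes(
    tibble::tibble(mip = 1:2, image = 1:2, excluded = c(FALSE, TRUE))
  ), "two")
  expect_s3_class(glance(f3), "tbl_df")
})

test_that("identical loaded/unloaded distributions classify as open everywhere", {
  net <- generate_network(network_spec(domain_size_nm = 800, seed = 7))
  bins <- psd_bin_edges()
  img <- network_psd(net, bins)
  mip <- intrusion_to_psd(simulate_intrusion(net), bin_edges = bins)
  cl <- classify_pore_states(img, img, mip, mip)
  active <- cl$state[cl$state != "negligible"]
  expect_true(all(active == "open"))
  expect_gt(length(active), 0)
})

test_that("pore filling classifies as filled, surface blocking as blocked with external voids", {
  net <- generate_network(network_spec(domain_size_nm = 1200, seed = 7))
  bins <- psd_bin_edges()
  hg <- mercury_params()
  img_unl <- network_psd(net, bins)
  mip_unl <- intrusion_to_psd(simulate_intrusion(net, hg), hg, bins)

  filled_net <- apply_loading(net, loading_mode("pore_filling", 0.9))
  cl_f <- classify_pore_states(
    img_unl, network_psd(filled_net, bins),
    mip_unl, intrusion_to_psd(simulate_intrusion(filled_net, hg), hg, bins)
  )
  wt <- cl_f$img_unloaded + cl_f$mip_unloaded
  expect_gte(sum(wt[cl_f$state == "filled"]) / sum(wt), 0.9)
  sub <- cl_f$bin_hi_nm <= 500
  expect_gt(sum(cl_f$img_unloaded[sub & cl_f$state == "filled"]) /
              sum(cl_f$img_unloaded[sub]), 0.5)
  expect_false(any(cl_f$state == "external_void"))

  blocked_net <- apply_loading(net, loading_mode("surface_blocking", 0.3),
                               seed = 3)
  cl_b <- classify_pore_states(
    img_unl, network_psd(blocked_net, bins),
    mip_unl, intrusion_to_psd(simulate_intrusion(blocked_net, hg), hg, bins)
  )
  wt_b <- cl_b$img_unloaded + cl_b$mip_unloaded
  expect_gte(sum(wt_b[cl_b$state == "blocked"]) / sum(wt_b), 0.9)
  expect_true(any(cl_b$state == "external_void" & cl_b$bin_lo_nm >= 500))

  expect_error(
    classify_pore_states(img_unl, img_unl, mip_unl,
                         intrusion_to_psd(simulate_intrusion(net, hg), hg,
                                          psd_bin_edges(10, 1e5, 10))),
    "identical bins"
  )
})

test_that("the measured diameter ratio grows with the generator's body/throat ratio", {
  ratios <- c(2, 6)
  measured <- vapply(ratios, function(r) {
    net <- generate_network(network_spec(domain_size_nm = 800,
                                         throat_to_body_ratio = 1 / r,
                                         seed = 31))
    mip <- psd_summary(
      intrusion_to_psd(simulate_intrusion(net), bin_edges = psd_bin_edges())
    )$avg_diameter_4VA_nm
    mean(net$bodies$diameter_nm) / mip
  }, numeric(1))
  expect_gt(measured[2], measured[1])
})
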