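# Image cleanup (destriping, bandpass) and segmentation.

render_clean <- function(seed = 3, px = 256, porosity = 0.6) {
  net <- generate_network(network_spec(domain_size_nm = 1000,
                                       target_porosity = porosity,
                                       seed = seed))
  render_cross_section(
    net, 500,
    render = render_spec(image_px = px, noise_sd = 0, curtain_amplitude = 0,
                         gradient_amplitude = 0)
  )
}

test_that("destriping removes stripes without touching horizontal structure", {
  sl <- render_clean()
  clean <- sl$image
  stripes <- 0.15 * sin(2 * pi * (1:256) * 0.04) +
    0.08 * sin(2 * pi * (1:256) * 0.11 + 1)
  striped <- cross_section(clean$pixels +
                             matrix(stripes, 256, 256, byrow = TRUE), 10)
  out <- destripe(striped)
  cv <- function(m) var(colMeans(m))
  reduction <- 1 - cv(out$pixels - clean$pixels) /
    cv(striped$pixels - clean$pixels)
  expect_gte(reduction, 0.8)
  # mean intensity preserved
  expect_lt(abs(mean(out$pixels) - mean(striped$pixels)) /
              mean(striped$pixels), 0.01)
  # purely horizontal bands (x-invariant content) pass through unchanged
  bands <- cross_section(matrix(0.5 + 0.2 * sin(2 * pi * (1:256) / 40),
                                256, 256), 10)
  out_b <- destripe(bands)
  expect_lt(sqrt(mean((out_b$pixels - bands$pixels)^2)), 0.02 * 0.4)
})

test_that("destriping converges to the identity as damping vanishes", {
  sl <- render_clean(seed = 8)
  tiny <- destripe(sl$image, damping_coefficient = 1e-6)
  # in the limit only the strictly column-constant component is removed
  col_rms <- sqrt(mean((colMeans(sl$image$pixels) -
                          mean(sl$image$pixels))^2))
  expect_lt(sqrt(mean((tiny$pixels - sl$image$pixels)^2)), 1.5 * col_rms)
  strong <- destripe(sl$image, damping_coefficient = 4)
  expect_gt(sqrt(mean((strong$pixels - sl$image$pixels)^2)),
            sqrt(mean((tiny$pixels - sl$image$pixels)^2)))
})

test_that("destriping rejects images smaller than the wavelet support allows", {
  small <- cross_section(matrix(runif(32 * 32), 32, 32), 10)
  expect_error(destripe(small, wavelet = "db15", levels = 3), "smaller")
  expect_silent(destripe(small, wavelet = "db2", levels = 3))
})

test_that("bandpass preserves constants, removes gradients, keeps pore contrast", {
  const <- cross_section(matrix(0.5, 64, 64), 10)
  expect_equal(bandpass(const, 30, 2)$pixels, matrix(0.5, 64, 64),
               tolerance = 1e-12)

  grad <- cross_section(outer(seq(0, 0.2, length.out = 256),
                              seq(0, 0.1, length.out = 256), "+"), 10)
  res <- bandpass(grad, 100, 2)
  expect_lt(diff(range(res$pixels)), 0.1 * diff(range(grad$pixels)))

  # two discs + gradient: contrast matches the gradient-free filtered render
  disc <- matrix(0.65, 256, 256)
  for (cc in list(c(80, 80), c(180, 170))) {
    dd <- outer((1:256 - cc[1])^2, (1:256 - cc[2])^2, "+")
    disc[dd <= 20^2] <- 0.25
  }
  in_disc <- disc == 0.25
  contrast <- function(m) mean(m[!in_disc]) - mean(m[in_disc])
  with_grad <- bandpass(cross_section(disc + grad$pixels, 10), 100, 2)
  without <- bandpass(cross_section(disc, 10), 100, 2)
  expect_lt(abs(contrast(with_grad$pixels) - contrast(without$pixels)),
            0.1 * contrast(disc))
  expect_error(bandpass(grad, 2, 100), "exceed")
})

test_that("segmentation reproduces a noiseless two-level render exactly and is robust to noise", {
  sl <- render_clean(seed = 21)
  mask <- segment(sl$image, n_superpixels = 400)
  # superpixels quantize boundaries: demand near-exact agreement
  expect_gt(mean(mask$mask == sl$mask), 0.995)
  expect_gt(sum(mask$mask & sl$mask) / sum(mask$mask | sl$mask), 0.99)

  net <- generate_network(network_spec(domain_size_nm = 1000, seed = 21))
  noisy <- render_cross_section(
    net, 500,
    render = render_spec(image_px = 256, noise_sd = 0.04,
                         curtain_amplitude = 0, gradient_amplitude = 0)
  )
  m2 <- segment(noisy$image, n_superpixels = 400)
  iou <- sum(m2$mask & noisy$mask) / sum(m2$mask | noisy$mask)
  expect_gte(iou, 0.90)

  # constant intensity offset does not change the segmentation
  shifted <- cross_section(noisy$image$pixels + 0.1,
                           noisy$image$pixel_size_nm)
  expect_identical(segment(shifted, n_superpixels = 400)$mask, m2$mask)

  # inverted contrast with the inverted rule gives the complement
  inv <- cross_section(1 - sl$image$pixels, sl$image$pixel_size_nm)
  m_inv <- segment(inv, n_superpixels = 400, threshold_rule = "above")
  expect_gt(mean(m_inv$mask == mask$mask), 0.999)

  const <- cross_section(matrix(0.4, 64, 64), 10)
  expect_error(segment(const), "constant|threshold")
})

test_that("outlier masks are excluded by the MAD rule but never the last of a cross section", {
  mk <- function(p) pore_mask(matrix(seq_len(100) <= p * 100, 10, 10), 10)
  masks <- list(mk(0.2), mk(0.2), mk(0.2), mk(0.21), mk(1.0))
  out <- exclude_outliers(masks)
  expect_identical(out$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  identical_masks <- list(mk(0.3), mk(0.3), mk(0.3))
  expect_false(any(exclude_outliers(identical_masks)$excluded))

  # a lone mask in its cross section survives even if it is the outlier
  out2 <- exclude_outliers(masks, cross_section = c(1, 1, 1, 1, 2))
  expect_false(out2$excluded[5])
  expect_error(exclude_outliers(list()), "No masks")
})
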