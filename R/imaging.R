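# Cross-section image cleanup and pore quantification.

# reflect-pad a matrix to dimensions divisible by `mult`
pad_reflect <- function(x, mult) {
  pad_to <- function(n) ceiling(n / mult) * mult
  pr <- pad_to(nrow(x)) - nrow(x)
  pc <- pad_to(ncol(x)) - ncol(x)
  if (pr > 0) x <- rbind(x, x[nrow(x):(nrow(x) - pr + 1), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, ncol(x):(ncol(x) - pc + 1), drop = FALSE])
  x
}

# damp near-zero vertical frequencies of a coefficient block: FFT along y,
# multiply rows by 1 - exp(-f^2 / (2 sigma^2)), inverse FFT.
damp_vertical_dc <- function(block, sigma, keep_dc_col = FALSE) {
  n <- nrow(block)
  f <- pmin(0:(n - 1), n - (0:(n - 1)))
  g <- 1 - exp(-f^2 / (2 * sigma^2))
  fc <- stats::mvfft(block)
  if (keep_dc_col) {
    # leave the f_x = 0 column (true image mean / horizontal bands) alone
    m <- ncol(block)
    fx <- pmin(0:(m - 1), m - (0:(m - 1)))
    cols <- which(fx != 0)
    fc2 <- stats::fft(block)           # full 2D FFT
    fc2[, cols] <- fc2[, cols] * g
    return(Re(stats::fft(fc2, inverse = TRUE)) / length(block))
  }
  Re(stats::mvfft(fc * g, inverse = TRUE)) / n
}

#' Remove vertical curtaining stripes (wavelet-FFT filter)
#'
#' Ion-milled cross sections carry vertical stripe artifacts ("curtaining").
#' The image is decomposed with a multilevel Daubechies wavelet transform;
#' in each level's vertical-detail band (horizontal high-pass, vertical
#' low-pass -- where y-invariant stripes concentrate) the FFT along the
#' stripe axis is damped around zero frequency with a Gaussian of width
#' `damping_coefficient`, and the image is reconstructed. Stripe components
#' coarser than the deepest detail level are damped the same way in the
#' residual approximation band (sparing its mean and purely horizontal
#' structure), which extends the filter to arbitrarily wide stripes without
#' requiring more decomposition levels than the wavelet support allows.
#'
#' @param img A [cross_section()].
#' @param wavelet One of `"db2"`, `"db4"`, `"db8"`, `"db15"` (default
#'   `"db15"`, 15-tap-pair Daubechies).
#' @param levels Decomposition depth; default: the deepest the image size
#'   and wavelet support allow, capped at 5.
#' @param damping_coefficient Gaussian damping width (frequency samples);
#'   larger removes wider-band stripe energy. Default 4.
#' @return A destriped `cross_section` of the same size.
#' @export
destripe <- function(img, wavelet = "db15", levels = NULL,
                     damping_coefficient = 4) {
  stopifnot(inherits(img, "cross_section"))
  assert_positive(damping_coefficient, "damping_coefficient")
  f <- wavelet_filters(wavelet)
  x <- img$pixels
  max_lev <- floor(log2(min(dim(x)) / f$length))
  if (is.null(levels)) levels <- max(1L, min(5L, max_lev))
  if (levels < 1) rlang::abort("`levels` must be >= 1.")
  if (max_lev < levels) {
    rlang::abort(sprintf(
      "Image (%d x %d) is smaller than the %s support allows at %d levels.",
      nrow(x), ncol(x), wavelet, levels
    ))
  }
  xp <- pad_reflect(x, 2^levels)
  dec <- dwt2_forward(xp, wavelet, levels)
  for (l in seq_len(levels)) {
    dec$levels[[l]]$ad <- damp_vertical_dc(dec$levels[[l]]$ad,
                                           damping_coefficient)
  }
  # residual band: stripes are strictly y-invariant at every scale, so the
  # damping width is rescaled to the band height to spare genuine coarse
  # structure while still removing arbitrarily wide stripes
  sigma_res <- damping_coefficient * nrow(dec$approx) / nrow(xp)
  dec$approx <- damp_vertical_dc(dec$approx, sigma_res, keep_dc_col = TRUE)
  out <- dwt2_inverse(dec)[seq_len(nrow(x)), seq_len(ncol(x)), drop = FALSE]
  cross_section(out, img$pixel_size_nm,
                paste0(img$provenance, " | destriped"))
}

#' FFT bandpass filter to flatten brightness gradients
#'
#' Frequency-domain annular filter in the ImageJ convention: structures
#' larger than `low_cut_px` (slow brightness gradients) and smaller than
#' `high_cut_px` (pixel noise) are suppressed, pore-scale contrast in
#' between is preserved. The DC component is kept, so a constant image
#' passes through unchanged (mean-preserving).
#'
#' @param img A [cross_section()].
#' @param low_cut_px Structure size (px) above which features are removed.
#' @param high_cut_px Structure size (px) below which features are removed.
#' @return A filtered `cross_section`.
#' @export
bandpass <- function(img, low_cut_px = 100, high_cut_px = 2) {
  stopifnot(inherits(img, "cross_section"))
  assert_positive(low_cut_px, "low_cut_px")
  assert_positive(high_cut_px, "high_cut_px")
  if (low_cut_px <= high_cut_px) {
    rlang::abort("`low_cut_px` must exceed `high_cut_px` (large down to small).")
  }
  x0 <- img$pixels
  n0 <- nrow(x0); m0 <- ncol(x0)
  # mirror-pad so non-periodic gradients do not leak across the spectrum
  x <- rbind(x0, x0[n0:1, , drop = FALSE])
  x <- cbind(x, x[, m0:1, drop = FALSE])
  n <- nrow(x); m <- ncol(x)
  fy <- pmin(0:(n - 1), n - (0:(n - 1))) / n
  fx <- pmin(0:(m - 1), m - (0:(m - 1))) / m
  r2 <- outer(fy^2, fx^2, "+")            # squared frequency (cycles/px)
  # half-attenuation exactly at the two cutoff structure sizes
  keep_large <- exp(-log(2) / pmax(r2 * low_cut_px^2, 1e-300))
  keep_small <- exp(-log(2) * r2 * high_cut_px^2)
  mask <- keep_large * keep_small
  mask[1, 1] <- 1
  out <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / (n * m)
  out <- out[seq_len(n0), seq_len(m0), drop = FALSE]
  cross_section(out, img$pixel_size_nm,
                paste0(img$provenance, " | bandpass"))
}

# SLIC superpixels on a grayscale image. Returns an integer label matrix.
slic_labels <- function(x, n_superpixels, compactness, max_iter = 10) {
  n <- nrow(x); m <- ncol(x)
  S <- sqrt(n * m / n_superpixels)
  cy <- seq(S / 2, n, by = S); cx <- seq(S / 2, m, by = S)
  centers <- expand.grid(y = cy, x = cx)
  k <- nrow(centers)
  centers$i <- x[cbind(pmin(round(centers$y), n), pmin(round(centers$x), m))]
  yy <- matrix(seq_len(n), n, m)
  xx <- matrix(seq_len(m), n, m, byrow = TRUE)
  labels <- matrix(0L, n, m)
  for (iter in seq_len(max_iter)) {
    best <- matrix(Inf, n, m)
    labels[] <- 0L
    for (c_i in seq_len(k)) {
      y0 <- max(1L, floor(centers$y[c_i] - S)); y1 <- min(n, ceiling(centers$y[c_i] + S))
      x0 <- max(1L, floor(centers$x[c_i] - S)); x1 <- min(m, ceiling(centers$x[c_i] + S))
      ys <- y0:y1; xs <- x0:x1
      di <- x[ys, xs, drop = FALSE] - centers$i[c_i]
      dy <- yy[ys, xs, drop = FALSE] - centers$y[c_i]
      dx <- xx[ys, xs, drop = FALSE] - centers$x[c_i]
      d2 <- di^2 + (compactness / S)^2 * (dy^2 + dx^2)
      upd <- d2 < best[ys, xs]
      if (any(upd)) {
        b <- best[ys, xs]; b[upd] <- d2[upd]; best[ys, xs] <- b
        l <- labels[ys, xs]; l[upd] <- c_i; labels[ys, xs] <- l
      }
    }
    for (c_i in seq_len(k)) {
      sel <- labels == c_i
      if (any(sel)) {
        centers$y[c_i] <- mean(yy[sel])
        centers$x[c_i] <- mean(xx[sel])
        centers$i[c_i] <- mean(x[sel])
      }
    }
  }
  # orphans (unassigned pixels outside every window) -> nearest center
  if (any(labels == 0L)) {
    idx <- which(labels == 0L)
    for (p in idx) {
      d2 <- (yy[p] - centers$y)^2 + (xx[p] - centers$x)^2
      labels[p] <- which.min(d2)
    }
  }
  labels
}

#' Binary pore mask
#'
#' @param mask Logical matrix, `TRUE` = pore.
#' @param pixel_size_nm Pixel size (nm/px).
#' @param roi_bounds Optional integer vector `c(row0, row1, col0, col1)`
#'   recording the region of interest the mask was computed on.
#' @return A `pore_mask` object.
#' @export
pore_mask <- function(mask, pixel_size_nm, roi_bounds = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  assert_positive(pixel_size_nm, "pixel_size_nm")
  structure(
    list(mask = mask, pixel_size_nm = pixel_size_nm,
         roi_bounds = roi_bounds),
    class = "pore_mask"
  )
}

#' @export
print.pore_mask <- function(x, ...) {
  cat(sprintf("<pore_mask> %d x %d px, %.2f nm/px, 2D porosity %.3f\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_nm, mean(x$mask)))
  invisible(x)
}

#' Segment pores by SLIC superpixels and Otsu thresholding
#'
#' Computes SLIC superpixels (local k-means over intensity and position) on
#' the cleaned image, then labels each superpixel pore or solid by comparing
#' its mean intensity against a global Otsu threshold computed over the
#' superpixel means. Pores image darker than the solid in secondary-electron
#' contrast, so the default rule labels below-threshold superpixels as pore.
#'
#' @param img A [cross_section()] (ideally destriped and flattened).
#' @param n_superpixels Target number of superpixels (>= 2).
#' @param compactness SLIC spatial regularity weight; larger gives squarer
#'   superpixels (intensity is on the image's own scale).
#' @param threshold_rule `"below"` (pore = darker, default) or `"above"`.
#' @param threshold Optional explicit intensity threshold overriding Otsu
#'   (required for degenerate, near-constant images).
#' @param roi Optional `c(row0, row1, col0, col1)` region of interest;
#'   segmentation runs on the crop.
#' @param max_iter SLIC iterations.
#' @return A [pore_mask()].
#' @export
segment <- function(img, n_superpixels = 400, compactness = 0.2,
                    threshold_rule = c("below", "above"), threshold = NULL,
                    roi = NULL, max_iter = 10) {
  stopifnot(inherits(img, "cross_section"))
  threshold_rule <- match.arg(threshold_rule)
  if (n_superpixels < 2) rlang::abort("`n_superpixels` must be >= 2.")
  x <- img$pixels
  if (!is.null(roi)) {
    x <- x[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  labels <- slic_labels(x, n_superpixels, compactness, max_iter)
  means <- tapply(as.vector(x), as.vector(labels), mean)
  thr <- threshold %||% otsu_threshold(as.numeric(means))
  pore_ids <- as.integer(names(means))[
    if (threshold_rule == "below") means < thr else means > thr
  ]
  mask <- matrix(labels %in% pore_ids, nrow(x), ncol(x))
  pore_mask(mask, img$pixel_size_nm, roi_bounds = roi)
}

#' Exclude outlier masks by robust porosity screening
#'
#' Replaces by-eye outlier rejection with a quantified rule: masks whose 2D
#' porosity deviates from the formulation-wide median by more than
#' `k` median absolute deviations are flagged, except that the last
#' remaining mask of any cross section is never removed.
#'
#' @param masks List of [pore_mask()] objects.
#' @param cross_section Integer/character vector assigning each mask to a
#'   cross section (default: all one cross section).
#' @param k MAD multiplier.
#' @return A tibble with one row per mask: `cross_section`, `porosity`,
#'   `excluded`, and the kept masks in the `mask` list-column.
#' @export
exclude_outliers <- function(masks, cross_section = NULL, k = 3) {
  if (length(masks) == 0) rlang::abort("No masks supplied.")
  cross_section <- cross_section %||% rep(1L, length(masks))
  por <- vapply(masks, function(m) mean(m$mask), numeric(1))
  med <- stats::median(por)
  dev <- abs(por - med)
  # floor the robust scale so a degenerate MAD of 0 (most masks identical)
  # still flags gross outliers without tripping on numerical jitter
  scale <- max(stats::mad(por), 0.05 * max(med, .Machine$double.eps))
  flag <- dev > k * scale
  out <- tibble::tibble(
    cross_section = cross_section, porosity = por, excluded = flag,
    mask = masks
  )
  # never remove the last mask of a cross section
  out <- out |>
    dplyr::group_by(.data$cross_section) |>
    dplyr::mutate(
      excluded = if (all(.data$excluded)) {
        .data$excluded & dplyr::row_number() !=
          which.min(abs(.data$porosity - med))
      } else .data$excluded
    ) |>
    dplyr::ungroup()
  out
}

# 8-connected component labelling of a logical matrix via igraph.
label_components_8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, n, m)
  if (length(idx) == 0) return(lab)
  row_i <- ((idx - 1L) %% n) + 1L
  col_i <- ((idx - 1L) %/% n) + 1L
  shift_edges <- function(dr, dc) {
    ok <- row_i + dr >= 1L & row_i + dr <= n & col_i + dc >= 1L & col_i + dc <= m
    nb <- idx[ok] + dr + dc * n
    sel <- mask[nb]
    cbind(idx[ok][sel], nb[sel])
  }
  edges <- rbind(
    shift_edges(1L, 0L), shift_edges(0L, 1L),
    shift_edges(1L, 1L), shift_edges(-1L, 1L)
  )
  map <- integer(n * m)
  map[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(
    cbind(map[edges[, 1]], map[edges[, 2]]), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Pore metrics of a segmented cross section
#'
#' Pores are 8-connected components of the mask. Each pore's cross-sectional
#' area defines an equivalent disc whose radius then defines an equivalent
#' sphere (the spherical-pore convention); the specific pore volume follows
#' as `V_SP = V_PI / (W_I * H_I * D_AV * rho_T)`: the summed equivalent
#' sphere volumes normalized by the mass of an image-sized slab one average
#' pore diameter thick. Components smaller than `min_area_px` (noise
#' speckle) and pores touching the image border (censored size) contribute
#' to the 2D porosity but are excluded from the size statistics.
#'
#' @param mask A [pore_mask()].
#' @param tablet_density Tablet (envelope) density (g/cm^3).
#' @param min_area_px Minimum component area (px) counted as a pore.
#' @return An `image_pore_metrics` object: `$metrics` one-row tibble
#'   (`porosity_2d`, `n_pores`, `D_AV_nm`, `V_PI_mL`, `W_I_m`, `H_I_m`,
#'   `V_SP_mL_per_g`, `sample_mass_g`), `$pores` per-pore tibble.
#' @export
pore_metrics <- function(mask, tablet_density, min_area_px = 4) {
  stopifnot(inherits(mask, "pore_mask"))
  assert_positive(tablet_density, "tablet_density")
  px <- mask$pixel_size_nm
  m <- mask$mask
  lab <- label_components_8(m)
  porosity <- mean(m)
  n_comp <- max(lab)
  W_I <- ncol(m) * px * 1e-9
  H_I <- nrow(m) * px * 1e-9
  if (n_comp == 0) {
    rlang::warn("Mask contains no pores; size statistics are undefined.")
    pores <- tibble::tibble(
      id = integer(), area_nm2 = numeric(), eq_diameter_nm = numeric(),
      eq_sphere_vol_mL = numeric(), border = logical(), too_small = logical()
    )
    metrics <- tibble::tibble(
      porosity_2d = porosity, n_pores = 0L, D_AV_nm = NA_real_,
      V_PI_mL = 0, W_I_m = W_I, H_I_m = H_I, V_SP_mL_per_g = NA_real_,
      sample_mass_g = NA_real_
    )
    return(structure(list(metrics = metrics, pores = pores),
                     class = "image_pore_metrics"))
  }
  npx <- tabulate(lab[lab > 0], nbins = n_comp)
  border_ids <- unique(c(
    lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]
  ))
  border <- seq_len(n_comp) %in% setdiff(border_ids, 0L)
  too_small <- npx < min_area_px
  area_nm2 <- npx * px^2
  r_nm <- sqrt(area_nm2 / pi)
  vol_mL <- (4 / 3) * pi * r_nm^3 * NM3_TO_ML
  valid <- !border & !too_small
  pores <- tibble::tibble(
    id = seq_len(n_comp), area_nm2 = area_nm2, eq_diameter_nm = 2 * r_nm,
    eq_sphere_vol_mL = vol_mL, border = border, too_small = too_small
  )
  if (!any(valid)) {
    rlang::warn("All pores touch the border or are below the size cutoff.")
    D_AV <- NA_real_; V_PI <- 0; V_SP <- NA_real_; mass <- NA_real_
  } else {
    D_AV <- mean(2 * r_nm[valid])
    V_PI <- sum(vol_mL[valid])
    # mass of the imaged slab: area x one average pore diameter, at rho_T
    mass <- W_I * H_I * (D_AV * 1e-9) * tablet_density * 1e6
    V_SP <- V_PI / mass
  }
  metrics <- tibble::tibble(
    porosity_2d = porosity, n_pores = sum(valid), D_AV_nm = D_AV,
    V_PI_mL = V_PI, W_I_m = W_I, H_I_m = H_I, V_SP_mL_per_g = V_SP,
    sample_mass_g = mass
  )
  structure(list(metrics = metrics, pores = pores),
            class = "image_pore_metrics")
}

#' @export
print.image_pore_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<image_pore_metrics> porosity %.3f, %d pores, D_AV %.1f nm, V_SP %.3g mL/g\n",
    m$porosity_2d, m$n_pores, m$D_AV_nm, m$V_SP_mL_per_g
  ))
  invisible(x)
}

#' @rdname pore_metrics
#' @param x An `image_pore_metrics` object.
#' @param ... Unused.
#' @method glance image_pore_metrics
#' @export
glance.image_pore_metrics <- function(x, ...) x$metrics

#' @rdname pore_metrics
#' @method tidy image_pore_metrics
#' @export
tidy.image_pore_metrics <- function(x, ...) x$pores

#' Image-derived pore size distribution
#'
#' Accumulates equivalent-sphere pore volumes into diameter bins and
#' normalizes by the imaged slab mass (the same normalization as `V_SP`), so
#' the bins sum to the specific pore volume and share their schema with the
#' porosimetry distribution.
#'
#' @param metrics An `image_pore_metrics` from [pore_metrics()].
#' @param bin_edges Diameter bin edges (nm).
#' @return A `pore_psd` tibble; out-of-range pore volume is reported via
#'   attributes `overflow_below`/`overflow_above` and a warning.
#' @export
image_psd <- function(metrics, bin_edges = psd_bin_edges()) {
  stopifnot(inherits(metrics, "image_pore_metrics"))
  p <- metrics$pores
  valid <- !p$border & !p$too_small
  mass <- metrics$metrics$sample_mass_g
  if (!is.finite(mass)) {
    rlang::abort("Metrics carry no valid pores; cannot build a distribution.")
  }
  res <- bin_volumes(p$eq_diameter_nm[valid],
                     p$eq_sphere_vol_mL[valid] / mass, bin_edges)
  if (res$below + res$above > 0) {
    rlang::warn(sprintf(
      "%.3g mL/g of pore volume fell outside the bin range.",
      res$below + res$above
    ))
  }
  out <- res$psd
  attr(out, "overflow_below") <- res$below
  attr(out, "overflow_above") <- res$above
  out
}
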