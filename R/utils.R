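# Internal helpers shared across modules.

# nm^3 -> mL (1 nm^3 = 1e-21 cm^3 = 1e-21 mL)
NM3_TO_ML <- 1e-21

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn
assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be a finite positive number.", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name, closed_upper = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(if (closed_upper) x <= 1 else x < 1)
  if (!ok) rlang::abort(sprintf("`%s` must lie in [0,1].", name))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`; global RNG
# untouched. Every stochastic operation in the package routes through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite integer.")
  }
  withr::with_seed(as.integer(seed), expr)
}

# Exact Otsu threshold over a numeric vector: evaluates the between-class
# variance at every split of the sorted values (feasible because it runs on
# superpixel mean intensities, not raw pixels). Split-based, so the result
# is symmetric under intensity negation.
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) {
    rlang::abort(
      "Intensities are constant; Otsu thresholding is undefined. Supply an explicit threshold."
    )
  }
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  mu0 <- cs[k] / k
  mu1 <- (cs[n] - cs[k]) / (n - k)
  sigma_b <- k * (n - k) * (mu0 - mu1)^2
  best <- which.max(sigma_b)
  (x[best] + x[best + 1]) / 2
}

# Volume of the lens formed by two overlapping spheres (radii r1, r2, centre
# distance d). Handles containment and disjoint cases.
sphere_lens_volume <- function(r1, r2, d) {
  v <- numeric(length(d))
  rs <- pmin(r1, r2)
  inside <- d <= abs(r1 - r2)
  v[inside] <- (4 / 3) * pi * rs[inside]^3
  ov <- d < (r1 + r2) & !inside
  if (any(ov)) {
    a <- r1[ov]; b <- r2[ov]; dd <- d[ov]
    v[ov] <- pi * (a + b - dd)^2 *
      (dd^2 + 2 * dd * (a + b) - 3 * (a - b)^2) / (12 * dd)
  }
  v
}

# log-spaced diameter bin edges, n_per_decade bins per decade
#' Logarithmically spaced pore-diameter bin edges
#'
#' Default binning covers 5 nm to 360 um, the measurable range of a
#' low+high-pressure mercury intrusion run, with 20 bins per decade.
#'
#' @param d_min_nm,d_max_nm Range of diameters to cover (nm).
#' @param n_per_decade Number of bins per decade of diameter.
#' @return Numeric vector of strictly increasing bin edges (nm).
#' @export
psd_bin_edges <- function(d_min_nm = 5, d_max_nm = 360e3, n_per_decade = 20) {
  assert_positive(d_min_nm, "d_min_nm")
  assert_positive(d_max_nm, "d_max_nm")
  if (d_max_nm <= d_min_nm) rlang::abort("`d_max_nm` must exceed `d_min_nm`.")
  n <- ceiling(log10(d_max_nm / d_min_nm) * n_per_decade)
  10^seq(log10(d_min_nm), log10(d_max_nm), length.out = n + 1)
}

# Shared constructor for pore size distribution tibbles.
new_psd <- function(bin_lo_nm, bin_hi_nm, spec_vol_mL_per_g) {
  out <- tibble::tibble(
    bin_lo_nm = bin_lo_nm,
    bin_hi_nm = bin_hi_nm,
    spec_vol_mL_per_g = spec_vol_mL_per_g
  )
  class(out) <- c("pore_psd", class(out))
  out
}

# Accumulate volumes (already in the target unit) into diameter bins.
# Returns list(psd rows, overflow volume below/above range).
bin_volumes <- function(diam_nm, vol, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    rlang::abort("`bin_edges` must be strictly increasing.")
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(diam_nm, bin_edges, rightmost.closed = TRUE)
  below <- sum(vol[idx == 0])
  above <- sum(vol[idx > nb])
  keep <- idx >= 1L & idx <= nb
  binned <- numeric(nb)
  if (any(keep)) {
    agg <- rowsum(vol[keep], group = idx[keep])
    binned[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(
    psd = new_psd(bin_edges[-length(bin_edges)], bin_edges[-1], binned),
    below = below, above = above
  )
}
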