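#' Mercury intrusion parameters
#'
#' Surface tension and contact angle of mercury against the sample. Mercury
#' is non-wetting, so the contact angle must exceed 90 degrees; the
#' conventional values 485 mN/m and 130 degrees are the defaults.
#'
#' @param gamma_mN_m Mercury surface tension (mN/m).
#' @param theta_deg Mercury contact angle (degrees), in (90, 180).
#' @return A `mercury_params` list.
#' @export
mercury_params <- function(gamma_mN_m = 485, theta_deg = 130) {
  assert_positive(gamma_mN_m, "gamma_mN_m")
  if (theta_deg <= 90 || theta_deg >= 180) {
    rlang::abort("`theta_deg` must lie in (90, 180): mercury must be non-wetting.")
  }
  structure(
    list(gamma_mN_m = gamma_mN_m, theta_deg = theta_deg),
    class = "mercury_params"
  )
}

#' Young-Laplace pressure/diameter conversion
#'
#' `P = -4 * gamma * cos(theta) / d`: the pressure needed to force a
#' non-wetting liquid into a cylindrical opening of diameter `d`. Positive
#' because cos(theta) < 0 for a non-wetting contact angle.
#'
#' @param P_Pa Applied pressure (Pa).
#' @param hg A [mercury_params()].
#' @return `pressure_to_diameter()`: capillary diameter (nm);
#'   `diameter_to_pressure()`: pressure (Pa).
#' @export
pressure_to_diameter <- function(P_Pa, hg = mercury_params()) {
  stopifnot(inherits(hg, "mercury_params"))
  assert_positive(P_Pa, "P_Pa")
  # gamma mN/m -> N/m is 1e-3; d m -> nm is 1e9
  -4e6 * hg$gamma_mN_m * cos(hg$theta_deg * pi / 180) / P_Pa
}

#' @rdname pressure_to_diameter
#' @param d_nm Capillary diameter (nm).
#' @export
diameter_to_pressure <- function(d_nm, hg = mercury_params()) {
  stopifnot(inherits(hg, "mercury_params"))
  assert_positive(d_nm, "d_nm")
  -4e6 * hg$gamma_mN_m * cos(hg$theta_deg * pi / 180) / d_nm
}

#' Convert an intrusion curve to a pore size distribution
#'
#' Each incremental intruded volume between successive pressures is assigned
#' to the diameter bin containing the geometric mean of the two bounding
#' Young-Laplace diameters (log-scale midpoint, matching log-spaced bins);
#' the volume intruded at the first pressure is assigned to that pressure's
#' diameter. Total volume is conserved exactly.
#'
#' @param curve Tibble/data frame with ascending `pressure_Pa` and
#'   non-decreasing `cum_vol_mL_per_g`.
#' @param hg A [mercury_params()].
#' @param bin_edges Diameter bin edges (nm).
#' @return A `pore_psd` tibble. Volumes falling outside the bin range are
#'   reported via attributes `overflow_below`/`overflow_above` (mL/g) and a
#'   warning.
#' @export
intrusion_to_psd <- function(curve, hg = mercury_params(),
                             bin_edges = psd_bin_edges()) {
  p <- curve$pressure_Pa
  v <- curve$cum_vol_mL_per_g
  if (is.unsorted(p, strictly = FALSE)) {
    rlang::abort("Pressures must be ascending.")
  }
  bad <- which(diff(v) < 0)
  if (length(bad)) {
    rlang::abort(sprintf(
      "Cumulative volume decreases at rows %s.",
      paste(bad + 1, collapse = ", ")
    ))
  }
  d <- pressure_to_diameter(p, hg)
  inc <- c(v[1], diff(v))
  d_mid <- c(d[1], sqrt(d[-1] * d[-length(d)]))
  res <- bin_volumes(d_mid, inc, bin_edges)
  if (res$below + res$above > 0) {
    rlang::warn(sprintf(
      "%.3g mL/g fell outside the bin range (%.3g below, %.3g above); see attributes.",
      res$below + res$above, res$below, res$above
    ))
  }
  out <- res$psd
  attr(out, "overflow_below") <- res$below
  attr(out, "overflow_above") <- res$above
  out
}

#' Display smoothing of a pore size distribution
#'
#' Centred moving average of the per-bin volumes for plotting. Bins within
#' half a window of a local extremum (a strict sign change of the first
#' difference) are copied unchanged so that peaks are not flattened. Display
#' only: downstream computations always use the raw distribution.
#'
#' @param psd A `pore_psd` tibble, or a bare numeric series.
#' @param period Odd window length (>= 3).
#' @param protect_extrema Copy bins near local extrema unchanged?
#' @return Same type as `psd`, smoothed.
#' @export
smooth_for_display <- function(psd, period = 5, protect_extrema = TRUE) {
  if (period < 3 || period %% 2 == 0) {
    rlang::abort("`period` must be odd and >= 3.")
  }
  smooth_vec <- function(x) {
    n <- length(x)
    h <- (period - 1) / 2
    if (n < period) return(x)
    y <- x
    for (i in (h + 1):(n - h)) y[i] <- mean(x[(i - h):(i + h)])
    if (protect_extrema && n >= 3) {
      s <- sign(diff(x))
      ext <- which(s[-length(s)] * s[-1] < 0) + 1
      protect <- unique(unlist(lapply(ext, function(i) {
        max(1, i - h):min(n, i + h)
      })))
      y[protect] <- x[protect]
    }
    y
  }
  if (is.numeric(psd)) return(smooth_vec(psd))
  psd$spec_vol_mL_per_g <- smooth_vec(psd$spec_vol_mL_per_g)
  psd
}

#' Tablet porosity from mass, volume and skeletal density
#'
#' Consolidating the powder into a tablet removes interparticle voids, so
#' the tablet density against the skeletal density gives the intraparticle
#' porosity: `rho_T = m_T / V_T`, `P_I = 1 - rho_T / rho_S`,
#' `V_S = m_T / rho_S`, `V_P = V_T - V_S`.
#'
#' @param m_T Tablet mass (g).
#' @param V_T Tablet volume (cm^3).
#' @param rho_S Skeletal density (g/cm^3).
#' @return One-row tibble with `m_T`, `V_T`, `rho_T`, `rho_S`, `P_I`,
#'   `V_P`, `V_S`.
#' @export
tablet_porosity <- function(m_T, V_T, rho_S) {
  assert_positive(m_T, "m_T")
  assert_positive(V_T, "V_T")
  assert_positive(rho_S, "rho_S")
  rho_T <- m_T / V_T
  if (rho_T > rho_S) {
    rlang::abort("Tablet density exceeds skeletal density; impossible input.")
  }
  V_S <- m_T / rho_S
  tibble::tibble(
    m_T = m_T, V_T = V_T, rho_T = rho_T, rho_S = rho_S,
    P_I = 1 - rho_T / rho_S, V_P = V_T - V_S, V_S = V_S
  )
}

#' Mass-weighted average skeletal density of a two-phase solid
#'
#' @param rho_a,rho_b Component skeletal densities (g/cm^3).
#' @param w_a Mass fraction of component a, in \[0, 1\].
#' @return Averaged density `w_a * rho_a + (1 - w_a) * rho_b` (g/cm^3).
#' @export
averaged_skeletal_density <- function(rho_a, rho_b, w_a) {
  assert_positive(rho_a, "rho_a")
  assert_positive(rho_b, "rho_b")
  assert_fraction(w_a, "w_a")
  w_a * rho_a + (1 - w_a) * rho_b
}

# Largest-bottleneck ("breakthrough") intrusion diameter per body: process
# throats in decreasing diameter with a union-find, recording the diameter at
# which each body's cluster first touches the exterior. Bodies flagged
# interparticle are skipped: the consolidated MIP tablet has no
# interparticle voids.
breakthrough_diameters <- function(network) {
  b <- network$bodies
  n <- nrow(b)
  intra <- !b$interparticle
  th <- network$throats
  th <- th[!th$blocked & th$diameter_nm > 0, , drop = FALSE]
  keep <- intra[th$from] & (th$to == 0L | intra[pmax(th$to, 1L)])
  th <- th[keep, , drop = FALSE]
  ext <- n + 1L
  a_v <- th$from
  b_v <- ifelse(th$to == 0L, ext, th$to)
  ord <- order(th$diameter_nm, decreasing = TRUE)
  a_v <- a_v[ord]; b_v <- b_v[ord]; dia <- th$diameter_nm[ord]

  parent <- seq_len(ext)
  csize <- rep(1L, ext)
  members <- as.list(seq_len(ext))
  has_ext <- c(rep(FALSE, n), TRUE)
  breakthrough <- rep(NA_real_, n)

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(a_v)) {
    ra <- find(a_v[e]); rb <- find(b_v[e])
    if (ra == rb) next
    if (has_ext[ra] && !has_ext[rb]) {
      breakthrough[members[[rb]][members[[rb]] <= n]] <- dia[e]
    } else if (has_ext[rb] && !has_ext[ra]) {
      breakthrough[members[[ra]][members[[ra]] <= n]] <- dia[e]
    }
    if (csize[ra] < csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
    parent[rb] <- ra
    csize[ra] <- csize[ra] + csize[rb]
    members[[ra]] <- c(members[[ra]], members[[rb]])
    members[[rb]] <- integer(0)
    has_ext[ra] <- has_ext[ra] || has_ext[rb]
  }
  breakthrough
}

#' Simulate mercury intrusion into a pore network
#'
#' Percolation model of the ink-bottle effect: at each pressure, a body is
#' intruded iff a path of unblocked throats with Young-Laplace diameter at
#' least `d(P)` connects it to the exterior. A large body behind a narrow
#' throat therefore registers its whole volume at the throat's diameter,
#' which is exactly how porosimetry under-sizes body diameters.
#' Interparticle voids are excluded (the measured tablet is consolidated).
#'
#' @param network A `pore_network`.
#' @param hg A [mercury_params()].
#' @param pressures_Pa Ascending pressure schedule (Pa); the default scans
#'   the Young-Laplace diameters of [psd_bin_edges()] from large to small.
#' @return An `intrusion_curve` tibble (`pressure_Pa`, `cum_vol_mL_per_g`).
#' @export
simulate_intrusion <- function(network, hg = mercury_params(),
                               pressures_Pa = NULL) {
  stopifnot(inherits(network, "pore_network"))
  if (is.null(pressures_Pa)) {
    pressures_Pa <- diameter_to_pressure(rev(psd_bin_edges()), hg)
  }
  if (is.unsorted(pressures_Pa, strictly = FALSE)) {
    rlang::abort("`pressures_Pa` must be ascending.")
  }
  bt <- breakthrough_diameters(network)
  intra <- !network$bodies$interparticle
  vol <- sphere_volume(inner_diameters(network))
  mass <- network_volumes(network)$sample_mass_g
  d_sched <- pressure_to_diameter(pressures_Pa, hg)
  reached <- !is.na(bt)
  bt_r <- bt[reached & intra]
  v_r <- vol[reached & intra] * NM3_TO_ML / mass
  ord <- order(bt_r, decreasing = TRUE)
  bt_sorted <- bt_r[ord]
  v_cum <- cumsum(v_r[ord])
  # bodies intruded at pressure P: breakthrough >= d(P)
  idx <- findInterval(-d_sched, -bt_sorted)
  cum <- ifelse(idx == 0, 0, v_cum[pmax(idx, 1)])
  out <- tibble::tibble(pressure_Pa = pressures_Pa, cum_vol_mL_per_g = cum)
  class(out) <- c("intrusion_curve", class(out))
  out
}

#' Summary statistics of a pore size distribution
#'
#' Reports the total specific pore volume and two average-diameter
#' conventions: the porosimeter's cylindrical volume-to-surface average
#' `4V/A` (the volume-weighted harmonic mean diameter) and the
#' volume-weighted arithmetic mean. Bin diameters are taken at the
#' geometric bin midpoint.
#'
#' @param psd A `pore_psd` tibble.
#' @return One-row tibble: `total_volume_mL_per_g`,
#'   `avg_diameter_4VA_nm`, `avg_diameter_volwt_nm`.
#' @export
psd_summary <- function(psd) {
  v <- psd$spec_vol_mL_per_g
  d <- sqrt(psd$bin_lo_nm * psd$bin_hi_nm)
  tot <- sum(v)
  tibble::tibble(
    total_volume_mL_per_g = tot,
    avg_diameter_4VA_nm = if (tot > 0) tot / sum(v / d) else NA_real_,
    avg_diameter_volwt_nm = if (tot > 0) sum(v * d) / tot else NA_real_
  )
}

#' Read an instrument-style intrusion CSV
#'
#' Expects columns `pressure_Pa` and `cum_vol_mL_per_g`.
#'
#' @param path CSV file path.
#' @return An `intrusion_curve` tibble.
#' @export
read_intrusion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pressure_Pa", "cum_vol_mL_per_g")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf("CSV must have columns: %s.", paste(need, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("intrusion_curve", class(out))
  out
}

#' Read/write the shared pore-size-distribution CSV schema
#'
#' Both the porosimetry and the imaging pipelines emit this schema
#' (`bin_lo_nm`, `bin_hi_nm`, `spec_vol_mL_per_g`) so their distributions
#' can be compared bin-for-bin.
#'
#' @param path CSV file path.
#' @param psd A `pore_psd` tibble (for writing).
#' @return `read_psd_csv()` returns a `pore_psd` tibble.
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_lo_nm", "bin_hi_nm", "spec_vol_mL_per_g")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf("CSV must have columns: %s.", paste(need, collapse = ", ")))
  }
  new_psd(df$bin_lo_nm, df$bin_hi_nm, df$spec_vol_mL_per_g)
}

#' @rdname read_psd_csv
#' @export
write_psd_csv <- function(psd, path) {
  utils::write.csv(
    psd[c("bin_lo_nm", "bin_hi_nm", "spec_vol_mL_per_g")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname simulate_intrusion
#' @param object An `intrusion_curve` (for `autoplot`).
#' @param ... Unused.
#' @method autoplot intrusion_curve
#' @export
autoplot.intrusion_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pressure_Pa, .data$cum_vol_mL_per_g)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pressure (Pa)", y = "cumulative intruded volume (mL/g)")
}

#' @rdname psd_summary
#' @param object A `pore_psd` (for `autoplot`).
#' @param ... Unused.
#' @method autoplot pore_psd
#' @export
autoplot.pore_psd <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = sqrt(.data$bin_lo_nm * .data$bin_hi_nm),
                 y = .data$spec_vol_mL_per_g)
  ) +
    ggplot2::geom_col(width = 0.04) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pore diameter (nm)", y = "specific volume (mL/g)")
}
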