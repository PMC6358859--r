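#' Theoretical drug load of a formulation
#'
#' Drug load is the mass of loaded material over the total formulation mass,
#' `DL = m_M / (m_M + m_FCC)`.
#'
#' @param m_M Mass of loaded material (g).
#' @param m_FCC Mass of carrier (g).
#' @return Drug load as a fraction in \[0, 1).
#' @export
drug_load <- function(m_M, m_FCC) {
  if (any(m_M < 0) || any(m_FCC < 0)) rlang::abort("Masses must be >= 0.")
  if (any(m_M + m_FCC == 0)) rlang::abort("Masses cannot both be zero.")
  m_M / (m_M + m_FCC)
}

#' Reference mass-loss fraction
#'
#' Fraction of initial reference mass lost over the TGA evaluation window,
#' `f_ref = dm_ref / m_ref`.
#'
#' @param dm_ref Mass loss of the pure reference (mg).
#' @param m_ref Initial mass of the pure reference (mg).
#' @return Fraction in \[0, 1\].
#' @export
tga_reference_fraction <- function(dm_ref, m_ref) {
  assert_positive(m_ref, "m_ref")
  if (any(dm_ref < 0) || any(dm_ref > m_ref)) {
    rlang::abort("`dm_ref` must lie between 0 and `m_ref`.")
  }
  dm_ref / m_ref
}

#' Two-component TGA content deconvolution
#'
#' Solves the mixing system: total loss `dm_Tot = m_M * f_M + m_FCC * f_FCC`
#' with `m_M + m_FCC = m_Tot`, giving
#' `m_FCC = (dm_Tot - f_M * m_Tot) / (f_FCC - f_M)` and the drug load
#' `DL = m_M / m_Tot`.
#'
#' @param dm_Tot Total mass loss of the sample over the window (mg).
#' @param m_Tot Initial sample mass (mg).
#' @param refs A [tga_reference_set()].
#' @return A one-row tibble: `dm_Tot`, `m_M_mg`, `m_FCC_mg`, `DL_est`.
#' @export
tga_content <- function(dm_Tot, m_Tot, refs) {
  stopifnot(inherits(refs, "tga_reference_set"))
  assert_positive(m_Tot, "m_Tot")
  f_lo <- min(refs$f_M, refs$f_FCC) * m_Tot
  f_hi <- max(refs$f_M, refs$f_FCC) * m_Tot
  tol <- 1e-9 * m_Tot
  if (dm_Tot < f_lo - tol || dm_Tot > f_hi + tol) {
    rlang::abort(
      sprintf(
        "Observed loss %.4g mg is outside the feasible band [%.4g, %.4g] mg implied by the references.",
        dm_Tot, f_lo, f_hi
      )
    )
  }
  m_FCC <- (dm_Tot - refs$f_M * m_Tot) / (refs$f_FCC - refs$f_M)
  m_FCC <- pmin(pmax(m_FCC, 0), m_Tot)
  m_M <- m_Tot - m_FCC
  tibble::tibble(
    dm_Tot = dm_Tot, m_M_mg = m_M, m_FCC_mg = m_FCC, DL_est = m_M / m_Tot
  )
}

#' @rdname tga_content
#' @param trace A `tga_trace` tibble, e.g. from [simulate_tga()] or read
#'   from an instrument CSV.
#' @export
tga_content_from_trace <- function(trace, refs) {
  m0 <- stats::approx(trace$temp_C, trace$mass_mg, xout = refs$window_C[1])$y
  tga_content(tga_mass_loss(trace, refs$window_C), m_Tot = m0, refs = refs)
}

# least-squares slope of mass^2 vs time through the origin, restricted to the
# early-time Washburn regime (below `cutoff` of the plateau mass)
washburn_slope <- function(trace, cutoff = 0.9) {
  m_max <- max(trace$mass_g)
  keep <- trace$mass_g <= cutoff * m_max & trace$time_s > 0
  if (sum(keep) < 2) keep <- trace$time_s > 0
  t <- trace$time_s[keep]
  y <- trace$mass_g[keep]^2
  sum(t * y) / sum(t * t)
}

#' Calibrate the capillary constant from a perfectly wetting liquid
#'
#' A fully wetting probe liquid (conventionally n-hexane, cos(theta) = 1)
#' fixes the packing-dependent capillary constant:
#' `c = slope(m^2 vs t) * eta / (rho^2 * sigma)`.
#'
#' @param trace A `sorption_trace` tibble for the wetting liquid.
#' @param liquid A [liquid_props()] for the probe liquid.
#' @param cutoff Fraction of the plateau mass delimiting the linear
#'   early-time regime used in the fit.
#' @return The capillary constant `c` (same unit convention as used by
#'   [simulate_sorption()] and [washburn_contact_angle()]).
#' @export
calibrate_capillary_constant <- function(trace, liquid, cutoff = 0.9) {
  stopifnot(inherits(liquid, "liquid_props"))
  k <- washburn_slope(trace, cutoff)
  if (!is.finite(k) || k <= 0) {
    rlang::abort("Trace shows no uptake; cannot calibrate.")
  }
  k * liquid$viscosity_mPa_s /
    (liquid$density_kg_m3^2 * liquid$surface_tension_mN_m)
}

#' Contact angle from a Washburn sorption trace
#'
#' Inverts the capillary-rise relation
#' `cos(theta) = m^2 * eta / (c * rho^2 * sigma * t)` using the fitted slope
#' of squared mass against time. A fitted cosine above 1 indicates a
#' data-quality problem (e.g. miscalibrated `c`); it is clamped to
#' `theta = 0` with a warning.
#'
#' @param trace A `sorption_trace` tibble.
#' @param liquid A [liquid_props()] for the measured solution.
#' @param capillary_constant The constant from
#'   [calibrate_capillary_constant()].
#' @param cutoff Early-time regime cutoff (fraction of plateau mass).
#' @return Contact angle in degrees.
#' @export
washburn_contact_angle <- function(trace, liquid, capillary_constant,
                                   cutoff = 0.9) {
  stopifnot(inherits(liquid, "liquid_props"))
  assert_positive(capillary_constant, "capillary_constant")
  k <- washburn_slope(trace, cutoff)
  if (!is.finite(k) || k <= 0) {
    rlang::abort("Trace shows no uptake; contact angle is undefined (>= 90 degrees).")
  }
  cth <- k * liquid$viscosity_mPa_s /
    (capillary_constant * liquid$density_kg_m3^2 *
       liquid$surface_tension_mN_m)
  if (cth > 1 + 1e-12) {
    rlang::warn(sprintf(
      "Fitted cos(theta) = %.4f > 1; reporting 0 degrees. Check the capillary constant.",
      cth
    ))
  }
  acos(pmin(cth, 1)) * 180 / pi
}

#' Saturation analysis of a solvent-evaporation loading
#'
#' During evaporation the dissolved material reaches its solubility limit
#' when the remaining solvent volume falls to `V_sat = m_M / solubility`;
#' whatever solution is then outside the pores precipitates externally. The
#' carrier can hold `m_FCC * specific_pore_volume` of solution, so the
#' fraction of the saturated solution inside pores is
#' `pore_capacity / V_sat` (capped at 1).
#'
#' @param formulation A [formulation_record()] with solvent volume and
#'   solubility set.
#' @param specific_pore_volume Carrier pore volume per gram (mL/g).
#' @return A one-row tibble: saturation volume (mL), pore capacity (mL),
#'   fraction of solution inside pores, and flags for predicted external
#'   deposition and for material never fully dissolving.
#' @export
saturation_analysis <- function(formulation, specific_pore_volume) {
  assert_positive(specific_pore_volume, "specific_pore_volume")
  sol <- formulation$solubility_g_per_mL
  if (is.na(sol) || sol <= 0) rlang::abort("Solubility must be positive.")
  v_sat <- formulation$m_M / sol
  pore_capacity <- formulation$m_FCC * specific_pore_volume
  frac <- if (v_sat > 0) min(1, pore_capacity / v_sat) else 1
  tibble::tibble(
    label = formulation$label,
    V_sat_mL = v_sat,
    pore_capacity_mL = pore_capacity,
    fraction_in_pores = frac,
    external_deposition = frac < 1,
    never_fully_dissolved = !is.na(formulation$solvent_volume_mL) &&
      v_sat >= formulation$solvent_volume_mL
  )
}
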