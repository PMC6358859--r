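#' Formulation record
#'
#' Masses and solvent context of one loading batch: `m_M` grams of material
#' loaded onto `m_FCC` grams of carrier from `solvent_volume_mL` of solvent
#' in which the material dissolves up to `solubility_g_per_mL`.
#'
#' @param m_M Mass of loaded material (g).
#' @param m_FCC Mass of carrier (g).
#' @param solvent_volume_mL Solvent volume used for loading (mL).
#' @param solubility_g_per_mL Solubility of the material in the solvent
#'   (g/mL).
#' @param label Free-text batch label.
#' @return A one-row `formulation_record` tibble with derived total mass and
#'   drug load.
#' @export
formulation_record <- function(m_M, m_FCC, solvent_volume_mL = NA_real_,
                               solubility_g_per_mL = NA_real_, label = "") {
  if (m_M < 0 || m_FCC < 0) rlang::abort("Masses must be >= 0.")
  out <- tibble::tibble(
    label = label, m_M = m_M, m_FCC = m_FCC, m_Tot = m_M + m_FCC,
    DL = drug_load(m_M, m_FCC),
    solvent_volume_mL = solvent_volume_mL,
    solubility_g_per_mL = solubility_g_per_mL
  )
  class(out) <- c("formulation_record", class(out))
  out
}

#' Reference mass-loss fractions for TGA deconvolution
#'
#' Fractions of initial mass lost in the evaluation window by the pure
#' loaded material (`f_M`) and the pure carrier (`f_FCC`). They must differ,
#' otherwise the two-component mixing equation is not identifiable.
#'
#' @param f_M,f_FCC Mass-loss fractions in \[0, 1).
#' @param window_C Temperature window (degrees C) over which losses are
#'   evaluated; default 150-600.
#' @return A `tga_reference_set` list.
#' @export
tga_reference_set <- function(f_M, f_FCC, window_C = c(150, 600)) {
  assert_fraction(f_M, "f_M", closed_upper = FALSE)
  assert_fraction(f_FCC, "f_FCC", closed_upper = FALSE)
  if (f_M == f_FCC) {
    rlang::abort("`f_M` and `f_FCC` must differ (identifiability).")
  }
  structure(
    list(f_M = f_M, f_FCC = f_FCC, window_C = window_C),
    class = "tga_reference_set"
  )
}

# Smoothstep that is exactly 0 below `lo` and exactly 1 above `hi`, so the
# simulated losses are confined to the evaluation window at double precision.
smoothstep <- function(x, lo, hi) {
  u <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate a thermogravimetric trace of a loaded sample
#'
#' Total mass loss inside the reference window equals
#' `m_M * f_M + m_FCC * f_FCC` (two-component mixing); the loss of each
#' component follows a smooth ramp fully contained in the window, so the
#' deconvolution [tga_content()] inverts the simulation exactly at zero
#' noise.
#'
#' @param formulation A [formulation_record()].
#' @param refs A [tga_reference_set()].
#' @param noise_sd Gaussian noise on the balance readings (mg).
#' @param temp_C Temperature grid (degrees C).
#' @param seed Integer seed for the noise.
#' @return A `tga_trace` tibble (`temp_C`, `mass_mg`).
#' @export
simulate_tga <- function(formulation, refs, noise_sd = 0,
                         temp_C = seq(35, 950, by = 1), seed = 1) {
  stopifnot(inherits(refs, "tga_reference_set"))
  m_M_mg <- formulation$m_M * 1000
  m_FCC_mg <- formulation$m_FCC * 1000
  if (m_M_mg < 0 || m_FCC_mg < 0) rlang::abort("Masses must be >= 0.")
  w <- refs$window_C
  # component ramps strictly inside the window
  lo1 <- w[1] + 0.1 * diff(w); hi1 <- w[1] + 0.6 * diff(w)
  lo2 <- w[1] + 0.65 * diff(w); hi2 <- w[1] + 0.95 * diff(w)
  mass <- (m_M_mg + m_FCC_mg) -
    m_M_mg * refs$f_M * smoothstep(temp_C, lo1, hi1) -
    m_FCC_mg * refs$f_FCC * smoothstep(temp_C, lo2, hi2)
  if (noise_sd > 0) {
    mass <- mass + with_seed(seed, stats::rnorm(length(mass), sd = noise_sd))
  }
  out <- tibble::tibble(temp_C = temp_C, mass_mg = mass)
  class(out) <- c("tga_trace", class(out))
  out
}

#' Mass loss of a TGA trace over a temperature window
#'
#' @param trace A `tga_trace` tibble (`temp_C`, `mass_mg`).
#' @param window_C Temperature window (degrees C).
#' @return Mass loss (mg) between the window endpoints (linear
#'   interpolation).
#' @export
tga_mass_loss <- function(trace, window_C = c(150, 600)) {
  m <- stats::approx(trace$temp_C, trace$mass_mg, xout = window_C)$y
  if (any(is.na(m))) rlang::abort("Window extends beyond the trace.")
  m[1] - m[2]
}

#' Physical properties of a loading solution
#'
#' @param density_kg_m3 Density (kg/m^3).
#' @param viscosity_mPa_s Dynamic viscosity (mPa s).
#' @param surface_tension_mN_m Surface tension (mN/m).
#' @param temperature_C Measurement temperature (degrees C), informational.
#' @return A `liquid_props` list.
#' @export
liquid_props <- function(density_kg_m3, viscosity_mPa_s,
                         surface_tension_mN_m, temperature_C = NA_real_) {
  assert_positive(density_kg_m3, "density_kg_m3")
  assert_positive(viscosity_mPa_s, "viscosity_mPa_s")
  assert_positive(surface_tension_mN_m, "surface_tension_mN_m")
  structure(
    list(
      density_kg_m3 = density_kg_m3, viscosity_mPa_s = viscosity_mPa_s,
      surface_tension_mN_m = surface_tension_mN_m,
      temperature_C = temperature_C
    ),
    class = "liquid_props"
  )
}

#' Simulate a Washburn capillary-rise sorption trace
#'
#' Absorbed mass follows `m(t) = sqrt(cos(theta) * c * rho^2 * sigma * t /
#' eta)`, i.e. squared mass is linear in time, the regime the contact-angle
#' estimation inverts. A contact angle of 90 degrees or more gives a
#' zero-uptake trace (the liquid does not wet the powder).
#'
#' @param liquid A [liquid_props()].
#' @param contact_angle_deg Contact angle between liquid and powder
#'   (degrees).
#' @param capillary_constant Packing/instrument capillary constant `c`, the
#'   same unit convention as [calibrate_capillary_constant()] returns.
#' @param duration_s Trace duration (s).
#' @param n_points Number of samples, evenly spaced from 0 to `duration_s`.
#' @param noise_sd Gaussian noise on mass readings (g).
#' @param plateau_mass_g Optional saturation plateau: uptake is capped here.
#' @param seed Integer seed for the noise.
#' @return A `sorption_trace` tibble (`time_s`, `mass_g`).
#' @export
simulate_sorption <- function(liquid, contact_angle_deg, capillary_constant,
                              duration_s = 60, n_points = 121, noise_sd = 0,
                              plateau_mass_g = Inf, seed = 1) {
  stopifnot(inherits(liquid, "liquid_props"))
  assert_positive(capillary_constant, "capillary_constant")
  if (duration_s < 0) rlang::abort("`duration_s` must be >= 0.")
  t <- seq(0, duration_s, length.out = n_points)
  cth <- cos(contact_angle_deg * pi / 180)
  slope <- if (cth > 0) {
    cth * capillary_constant * liquid$density_kg_m3^2 *
      liquid$surface_tension_mN_m / liquid$viscosity_mPa_s
  } else 0
  m <- pmin(sqrt(slope * t), plateau_mass_g)
  if (noise_sd > 0) {
    m <- m + with_seed(seed, stats::rnorm(length(m), sd = noise_sd))
  }
  out <- tibble::tibble(time_s = t, mass_g = m)
  class(out) <- c("sorption_trace", class(out))
  out
}
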