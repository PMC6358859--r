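#' Calibrated cross-section image
#'
#' Thin container for a grayscale micrograph: a numeric matrix (rows = y,
#' columns = x, intensities nominally in \[0, 1\]) plus the pixel size.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size_nm Pixel edge length (nm/px).
#' @param provenance Free-text origin note.
#' @return A `cross_section` object.
#' @export
cross_section <- function(pixels, pixel_size_nm, provenance = "") {
  stopifnot(is.matrix(pixels))
  assert_positive(pixel_size_nm, "pixel_size_nm")
  if (any(!is.finite(pixels))) rlang::abort("Image intensities must be finite.")
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         provenance = provenance),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> %d x %d px, %.2f nm/px%s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
    if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else ""
  ))
  invisible(x)
}

#' Rendering parameters for synthetic cross sections
#'
#' Emulates the look of an ion-milled cross section imaged by SEM: dark pores
#' in a bright solid matrix, overlaid with vertical curtaining stripes (uneven
#' milling), a smooth brightness gradient (detector/charging geometry), and
#' Gaussian sensor noise.
#'
#' @param image_px Image edge length in pixels (square image).
#' @param pixel_size_nm Pixel size (nm/px); default spans the network domain.
#' @param pore_gray,solid_gray Intensities of pore and solid phases.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param curtain_amplitude Stripe pattern standard deviation (intensity).
#' @param curtain_band Stripe frequency band (cycles/px), low and high.
#' @param gradient_amplitude Peak-to-peak brightness gradient (intensity).
#' @param seed Integer seed for stripes, gradient orientation and noise.
#' @return A `render_spec` list.
#' @export
render_spec <- function(image_px = 384, pixel_size_nm = NULL,
                        pore_gray = 0.25, solid_gray = 0.65,
                        noise_sd = 0.04, curtain_amplitude = 0.08,
                        curtain_band = c(0.02, 0.15),
                        gradient_amplitude = 0.10, seed = 1) {
  if (pore_gray == solid_gray) rlang::abort("Gray levels must be distinct.")
  if (noise_sd < 0 || curtain_amplitude < 0 || gradient_amplitude < 0) {
    rlang::abort("Artifact amplitudes must be >= 0.")
  }
  structure(
    list(
      image_px = as.integer(image_px), pixel_size_nm = pixel_size_nm,
      pore_gray = pore_gray, solid_gray = solid_gray, noise_sd = noise_sd,
      curtain_amplitude = curtain_amplitude, curtain_band = curtain_band,
      gradient_amplitude = gradient_amplitude, seed = seed
    ),
    class = "render_spec"
  )
}

# band-limited column pattern, unit sd, length w
curtain_pattern <- function(w, band) {
  z <- stats::rnorm(w)
  f <- stats::fft(z)
  freq <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  keep <- abs(freq) >= band[1] & abs(freq) <= band[2]
  f[!keep] <- 0
  p <- Re(stats::fft(f, inverse = TRUE)) / w
  if (stats::sd(p) == 0) return(numeric(w))
  (p - mean(p)) / stats::sd(p)
}

#' Render a cross section of a pore network
#'
#' Slices the network with an axis-aligned plane; every pore body the plane
#' intersects contributes a disc of pore-level intensity, the rest of the
#' field is solid-level. FIB-SEM-style artifacts (vertical curtaining,
#' brightness gradient, noise) are then added per the [render_spec()]. The
#' ground-truth binary mask is returned alongside the image.
#'
#' @param network A `pore_network`.
#' @param offset_nm Plane position along `axis` (nm); must lie inside the
#'   domain.
#' @param axis `"z"`, `"y"` or `"x"`: the normal of the cutting plane.
#' @param render A [render_spec()].
#' @return A list: `image` (`cross_section`), `mask` (logical matrix, TRUE =
#'   pore), `porosity_2d` (mask area fraction).
#' @export
render_cross_section <- function(network, offset_nm, axis = "z",
                                 render = render_spec()) {
  stopifnot(inherits(network, "pore_network"))
  L <- network$domain_size_nm
  if (offset_nm < 0 || offset_nm > L) {
    rlang::abort("`offset_nm` lies outside the particle domain.")
  }
  axis <- match.arg(axis, c("x", "y", "z"))
  w <- render$image_px
  px <- render$pixel_size_nm %||% (L / w)

  b <- network$bodies
  coords <- switch(axis,
    z = cbind(b$x_nm, b$y_nm, b$z_nm),
    y = cbind(b$x_nm, b$z_nm, b$y_nm),
    x = cbind(b$y_nm, b$z_nm, b$x_nm)
  )
  r_in <- inner_diameters(network) / 2
  dz <- coords[, 3] - offset_nm
  dz <- dz - round(dz / L) * L
  hit <- abs(dz) < r_in
  mask <- matrix(FALSE, w, w)
  if (any(hit)) {
    disc_r <- sqrt(r_in[hit]^2 - dz[hit]^2)
    cx <- coords[hit, 1]; cy <- coords[hit, 2]
    for (i in seq_along(disc_r)) {
      rr <- disc_r[i]
      gx <- floor((cx[i] - rr) / px):ceiling((cx[i] + rr) / px)
      gy <- floor((cy[i] - rr) / px):ceiling((cy[i] + rr) / px)
      ux <- (gx + 0.5) * px - cx[i]
      uy <- (gy + 0.5) * px - cy[i]
      inside <- outer(uy^2, ux^2, "+") <= rr^2
      iy <- (gy %% w) + 1L; ix <- (gx %% w) + 1L
      sub <- which(inside, arr.ind = TRUE)
      if (nrow(sub)) mask[cbind(iy[sub[, 1]], ix[sub[, 2]])] <- TRUE
    }
  }

  img <- matrix(render$solid_gray, w, w)
  img[mask] <- render$pore_gray
  img <- with_seed(render$seed, {
    out <- img
    if (render$curtain_amplitude > 0) {
      stripes <- curtain_pattern(w, render$curtain_band)
      out <- out + render$curtain_amplitude *
        matrix(stripes, w, w, byrow = TRUE)
    }
    if (render$gradient_amplitude > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      u <- (seq_len(w) - 0.5) / w - 0.5
      g <- outer(u * sin(phi), u * cos(phi), "+")
      out <- out + render$gradient_amplitude * g / max(diff(range(g)), 1e-12)
    }
    if (render$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(w * w, sd = render$noise_sd), w, w)
    }
    out
  })

  list(
    image = cross_section(img, px, sprintf("synthetic slice %s=%g nm", axis, offset_nm)),
    mask = mask,
    porosity_2d = mean(mask)
  )
}

#' @rdname render_cross_section
#' @param object A `cross_section` (for `autoplot`).
#' @param ... Unused.
#' @method autoplot cross_section
#' @export
autoplot.cross_section <- function(object, ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object$pixels)), x = seq_len(ncol(object$pixels))
  )
  df$value <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("x (%.1f nm/px)", object$pixel_size_nm), y = "y",
      fill = "intensity"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
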