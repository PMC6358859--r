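# Confronting mercury intrusion with image analysis.

#' Body-to-throat diameter ratio
#'
#' Image analysis sees pore bodies (true cavity diameters) while mercury
#' intrusion registers every cavity at its largest entrance (throat); the
#' ratio of the two average diameters is therefore a geometric fingerprint
#' of the pore shape.
#'
#' When the image-side average comes from planar sections of near-spherical
#' cavities, the section discs systematically undersize the bodies: a random
#' plane through a sphere of diameter `D` shows a disc of mean diameter
#' `pi/4 * D`. `correct_stereology = TRUE` applies the inverse (Wicksell)
#' factor `4/pi` to the image-side average so that the ratio compares body
#' diameters with throat diameters on the same footing. The default is
#' `FALSE`, the raw particle-analyzer convention.
#'
#' @param D_AV_image_nm Average pore diameter from image analysis (nm).
#' @param D_AV_mip_nm Average pore diameter from porosimetry (nm).
#' @param correct_stereology Apply the `4/pi` section-to-sphere diameter
#'   de-biasing to the image-side average?
#' @return Dimensionless ratio.
#' @export
body_throat_ratio <- function(D_AV_image_nm, D_AV_mip_nm,
                              correct_stereology = FALSE) {
  assert_positive(D_AV_image_nm, "D_AV_image_nm")
  assert_positive(D_AV_mip_nm, "D_AV_mip_nm")
  if (correct_stereology) D_AV_image_nm <- D_AV_image_nm * 4 / pi
  D_AV_image_nm / D_AV_mip_nm
}

#' Correlate image- and porosimetry-derived specific pore volumes
#'
#' Ordinary least squares of the image-derived on the porosimetry-derived
#' specific pore volume across formulations, with explicit exclusion flags
#' (formulations with external crystallization violate the comparison's
#' premise and are carried in the report but not fitted). R^2 is the squared
#' Pearson correlation of the fitted pairs.
#'
#' @param pairs Tibble/data frame with columns `mip`, `image` (mL/g) and
#'   optionally `excluded` (logical) and `label`.
#' @return A `vsp_correlation` object; see [tidy()] and [glance()] methods.
#' @export
correlate_specific_volumes <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mip", "image") %in% names(pairs))) {
    rlang::abort("`pairs` needs columns `mip` and `image`.")
  }
  if (!"excluded" %in% names(pairs)) pairs$excluded <- FALSE
  used <- pairs[!pairs$excluded, , drop = FALSE]
  if (nrow(used) < 2) {
    rlang::abort("Need at least two non-excluded pairs to fit.")
  }
  fit <- stats::lm(image ~ mip, data = used)
  r2 <- stats::cor(used$mip, used$image)^2
  structure(
    list(pairs = pairs, fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), r_squared = r2),
    class = "vsp_correlation"
  )
}

#' @export
print.vsp_correlation <- function(x, ...) {
  cat(sprintf(
    "<vsp_correlation> slope %.3f, R^2 %.3f (%d fitted, %d excluded)\n",
    x$slope, x$r_squared, sum(!x$pairs$excluded), sum(x$pairs$excluded)
  ))
  invisible(x)
}

#' @rdname correlate_specific_volumes
#' @param x A `vsp_correlation`.
#' @param ... Unused.
#' @method tidy vsp_correlation
#' @export
tidy.vsp_correlation <- function(x, ...) x$pairs

#' @rdname correlate_specific_volumes
#' @method glance vsp_correlation
#' @export
glance.vsp_correlation <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_fitted = sum(!x$pairs$excluded), n_excluded = sum(x$pairs$excluded)
  )
}

#' @rdname correlate_specific_volumes
#' @param object A `vsp_correlation` (for `autoplot`).
#' @method autoplot vsp_correlation
#' @export
autoplot.vsp_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$mip, .data$image,
                               shape = .data$excluded)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = "specific pore volume, porosimetry (mL/g)",
      y = "specific pore volume, image analysis (mL/g)",
      shape = "excluded"
    )
}

#' Classify pore populations as open, filled, blocked or external voids
#'
#' Per diameter bin, compares loaded against unloaded distributions from
#' both methods. Image analysis sees every cavity the plane cuts; mercury
#' only sees what it can reach, and registers it at the throat diameter --
#' so the two methods hold their volume in different bins, and each method's
#' retention is judged on its own support, falling back to the method's
#' global retention where it never had volume in a bin. The labels follow
#' the qualitative logic of combining the two techniques: cavity visible in
#' the image and mercury-accessible = `open`; cavity volume gone from the
#' image = `filled` (material occupies it); cavity visible but mercury
#' access lost = `blocked`; volume newly appearing in the image above
#' `void_min_nm` with no mercury counterpart = `external_void`
#' (interparticle crystallization). "Lost" means the loaded volume falls
#' below `retention_threshold` of the unloaded volume.
#'
#' @param psd_unloaded_img,psd_loaded_img,psd_unloaded_mip,psd_loaded_mip
#'   `pore_psd` tibbles on identical bins.
#' @param retention_threshold Fraction of unloaded volume below which a bin
#'   counts as lost (default 0.5).
#' @param void_min_nm Diameter above which newly appearing image volume is
#'   attributed to interparticle voids (default 500).
#' @param negligible Bins whose volumes are below this fraction of the
#'   largest bin volume carry no signal and are labelled `negligible`.
#' @return Tibble with bins, the four volumes, retention fractions and a
#'   `state` label.
#' @export
classify_pore_states <- function(psd_unloaded_img, psd_loaded_img,
                                 psd_unloaded_mip, psd_loaded_mip,
                                 retention_threshold = 0.5,
                                 void_min_nm = 500,
                                 negligible = 1e-3) {
  psds <- list(psd_unloaded_img, psd_loaded_img, psd_unloaded_mip,
               psd_loaded_mip)
  edges <- lapply(psds, function(p) cbind(p$bin_lo_nm, p$bin_hi_nm))
  if (!all(vapply(edges[-1], function(e) isTRUE(all.equal(e, edges[[1]])),
                  logical(1)))) {
    rlang::abort("All four distributions must share identical bins.")
  }
  v <- tibble::tibble(
    bin_lo_nm = psd_unloaded_img$bin_lo_nm,
    bin_hi_nm = psd_unloaded_img$bin_hi_nm,
    img_unloaded = psd_unloaded_img$spec_vol_mL_per_g,
    img_loaded = psd_loaded_img$spec_vol_mL_per_g,
    mip_unloaded = psd_unloaded_mip$spec_vol_mL_per_g,
    mip_loaded = psd_loaded_mip$spec_vol_mL_per_g
  )
  eps <- negligible * max(c(v$img_unloaded, v$mip_unloaded, v$img_loaded), 0)
  global_ret <- function(loaded, unloaded) {
    if (sum(unloaded) > 0) sum(loaded) / sum(unloaded) else NA_real_
  }
  img_global <- global_ret(v$img_loaded, v$img_unloaded)
  mip_global <- global_ret(v$mip_loaded, v$mip_unloaded)
  retained <- function(loaded, unloaded) {
    ifelse(unloaded > eps, loaded / unloaded, NA_real_)
  }
  v$img_retention <- retained(v$img_loaded, v$img_unloaded)
  v$mip_retention <- retained(v$mip_loaded, v$mip_unloaded)
  img_has <- v$img_unloaded > eps
  mip_has <- v$mip_unloaded > eps
  # accessibility signal for a bin: mercury's own retention there if it ever
  # held volume there, otherwise its global retention (the ink-bottle shift
  # places body volume at throat bins, so supports rarely coincide)
  mip_sig <- ifelse(mip_has, v$mip_retention, mip_global)
  img_kept <- img_has & v$img_retention >= retention_threshold
  img_lost <- img_has & v$img_retention < retention_threshold
  img_gained <- v$img_loaded > pmax((1 + retention_threshold) * v$img_unloaded, eps)

  v$state <- dplyr::case_when(
    img_gained & v$bin_hi_nm > void_min_nm &
      v$mip_loaded <= pmax(v$mip_unloaded, eps) ~ "external_void",
    img_kept & mip_sig >= retention_threshold ~ "open",
    img_kept ~ "blocked",
    img_lost ~ "filled",
    mip_has & v$mip_retention >= retention_threshold ~ "open",
    mip_has & img_global >= retention_threshold ~ "blocked",
    mip_has ~ "filled",
    v$img_loaded <= eps ~ "negligible",
    .default = "indeterminate"
  )
  v
}
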