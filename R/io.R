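# File interchange: images, networks, traces.

#' Read and write calibrated grayscale images
#'
#' Images travel as 16-bit grayscale TIFF (or PNG) with the pixel size
#' recorded in a JSON sidecar (`<image>.json`, field `pixel_size_nm`), since
#' neither format reliably carries physical calibration.
#'
#' @param path Image file path (`.tif`/`.tiff` or `.png`).
#' @param img A [cross_section()] (for writing). Intensities are clipped to
#'   \[0, 1\] on write.
#' @param pixel_size_nm Pixel size override when reading an image without a
#'   sidecar.
#' @return `read_cross_section()` returns a `cross_section`.
#' @export
read_cross_section <- function(path, pixel_size_nm = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- pixel_size_nm
  sidecar <- paste0(path, ".json")
  if (is.null(px) && file.exists(sidecar)) {
    px <- jsonlite::read_json(sidecar)$pixel_size_nm
  }
  if (is.null(px)) {
    rlang::abort("Pixel size unknown: supply `pixel_size_nm` or a JSON sidecar.")
  }
  mat <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        rlang::abort("Package 'tiff' is required to read TIFF files.")
      }
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        rlang::abort("Package 'png' is required to read PNG files.")
      }
      png::readPNG(path)
    },
    rlang::abort("Unsupported image format; use TIFF or PNG.")
  )
  if (length(dim(mat)) == 3) mat <- mat[, , 1]
  cross_section(mat, px, provenance = path)
}

#' @rdname read_cross_section
#' @export
write_cross_section <- function(img, path) {
  stopifnot(inherits(img, "cross_section"))
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(img$pixels, 0), 1)
  switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        rlang::abort("Package 'tiff' is required to write TIFF files.")
      }
      tiff::writeTIFF(x, path, bits.per.sample = 16)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        rlang::abort("Package 'png' is required to write PNG files.")
      }
      png::writePNG(x, path)
    },
    rlang::abort("Unsupported image format; use TIFF or PNG.")
  )
  jsonlite::write_json(
    list(pixel_size_nm = img$pixel_size_nm, provenance = img$provenance),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Write a binary pore mask as PNG (0/255)
#'
#' @param mask A [pore_mask()].
#' @param path PNG file path.
#' @export
write_pore_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pore_mask"))
  if (!requireNamespace("png", quietly = TRUE)) {
    rlang::abort("Package 'png' is required to write PNG files.")
  }
  png::writePNG(mask$mask * 1.0, path)
  invisible(path)
}

#' Serialize a pore network to JSON
#'
#' Nodes and edges with diameters in nm, plus domain metadata: a plain
#' interchange format for the synthetic ground truth.
#'
#' @param network A `pore_network`.
#' @param path JSON file path.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "pore_network"))
  jsonlite::write_json(
    list(
      domain_size_nm = network$domain_size_nm,
      skeletal_density = network$skeletal_density,
      deposit_density = network$deposit_density,
      porosity = network$porosity,
      lattice_a_nm = network$lattice_a_nm,
      bodies = network$bodies,
      throats = network$throats
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_network_json
#' @return `read_network_json()` returns a `pore_network`.
#' @export
read_network_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_pore_network(
    tibble::as_tibble(j$bodies), tibble::as_tibble(j$throats),
    j$domain_size_nm, j$skeletal_density, j$porosity, j$lattice_a_nm,
    deposit_density = j$deposit_density %||% 1.0
  )
}

#' Read and write instrument-style trace CSVs
#'
#' TGA traces use headers `temp_C,mass_mg`; sorption traces use
#' `time_s,mass_g`.
#'
#' @param path CSV file path.
#' @param trace The trace tibble (for writing).
#' @return Readers return the corresponding trace tibble.
#' @export
read_tga_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("temp_C", "mass_mg") %in% names(df))) {
    rlang::abort("TGA CSV must have columns temp_C, mass_mg.")
  }
  out <- tibble::as_tibble(df[c("temp_C", "mass_mg")])
  class(out) <- c("tga_trace", class(out))
  out
}

#' @rdname read_tga_csv
#' @export
read_sorption_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "mass_g") %in% names(df))) {
    rlang::abort("Sorption CSV must have columns time_s, mass_g.")
  }
  out <- tibble::as_tibble(df[c("time_s", "mass_g")])
  class(out) <- c("sorption_trace", class(out))
  out
}

#' @rdname read_tga_csv
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a formulation record from YAML
#'
#' Expects fields `m_M`, `m_FCC` and optionally `solvent_volume_mL`,
#' `solubility_g_per_mL`, `label`.
#'
#' @param path YAML file path.
#' @return A [formulation_record()].
#' @export
read_formulation_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    rlang::abort("Package 'yaml' is required to read formulation records.")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$m_M) || is.null(y$m_FCC)) {
    rlang::abort("Formulation YAML must define m_M and m_FCC.")
  }
  formulation_record(
    m_M = y$m_M, m_FCC = y$m_FCC,
    solvent_volume_mL = y$solvent_volume_mL %||% NA_real_,
    solubility_g_per_mL = y$solubility_g_per_mL %||% NA_real_,
    label = y$label %||% ""
  )
}
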