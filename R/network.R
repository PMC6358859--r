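#' Specify a synthetic pore network
#'
#' The generator emulates the cavity structure of a functionalized calcium
#' carbonate (FCC) microparticle: an approximately close-packed arrangement of
#' near-spherical pore bodies (~60% v/v porosity, body diameters around
#' 100 nm) connected through throats several times narrower than the bodies.
#'
#' @param n_bodies Optional body count; when `NULL` it is derived from
#'   `domain_size_nm`, `target_porosity` and the diameter distribution.
#' @param body_median_nm Median pore-body diameter (nm).
#' @param body_gsd Geometric standard deviation of the log-normal body
#'   diameter distribution (dimensionless, > 1 for spread).
#' @param throat_to_body_ratio Throat diameter as a fraction of the smaller
#'   adjacent body diameter, in (0, 1]. Default 1/4.7, the measured
#'   body-to-throat diameter ratio of unloaded FCC.
#' @param target_porosity Intraparticle porosity (volume fraction) to hit.
#' @param core_fraction Fraction of lattice sites replaced by solid,
#'   non-porous cores (FCC particles keep a calcite starter core).
#' @param domain_size_nm Edge length of the cubic particle domain (nm).
#' @param accessible_fraction Fraction of exterior throats kept open.
#' @param skeletal_density Skeletal density of the solid phase (g/cm^3).
#' @param jitter Positional jitter of lattice sites, as a fraction of the
#'   lattice constant.
#' @param seed Integer seed; all randomness in `generate_network()` flows
#'   from it.
#' @return A `network_spec` list.
#' @export
network_spec <- function(n_bodies = NULL,
                         body_median_nm = 100,
                         body_gsd = 1.25,
                         throat_to_body_ratio = 1 / 4.7,
                         target_porosity = 0.60,
                         core_fraction = 0,
                         domain_size_nm = 2000,
                         accessible_fraction = 1,
                         skeletal_density = 2.95,
                         jitter = 0.04,
                         seed = 1) {
  assert_positive(body_median_nm, "body_median_nm")
  if (body_gsd < 1) rlang::abort("`body_gsd` must be >= 1.")
  if (throat_to_body_ratio <= 0 || throat_to_body_ratio > 1) {
    rlang::abort("`throat_to_body_ratio` must lie in (0, 1].")
  }
  if (target_porosity <= 0 || target_porosity >= 1) {
    rlang::abort("`target_porosity` must lie in (0, 1).")
  }
  assert_fraction(core_fraction, "core_fraction")
  assert_fraction(accessible_fraction, "accessible_fraction")
  assert_positive(domain_size_nm, "domain_size_nm")
  assert_positive(skeletal_density, "skeletal_density")
  structure(
    list(
      n_bodies = n_bodies, body_median_nm = body_median_nm,
      body_gsd = body_gsd, throat_to_body_ratio = throat_to_body_ratio,
      target_porosity = target_porosity, core_fraction = core_fraction,
      domain_size_nm = domain_size_nm,
      accessible_fraction = accessible_fraction,
      skeletal_density = skeletal_density, jitter = jitter, seed = seed
    ),
    class = "network_spec"
  )
}

# Sphere volume from diameter (nm^3).
sphere_volume <- function(d) pi / 6 * d^3

new_pore_network <- function(bodies, throats, domain_size_nm,
                             skeletal_density, porosity, lattice_a_nm,
                             deposit_density = 1.0) {
  structure(
    list(
      bodies = bodies, throats = throats,
      domain_size_nm = domain_size_nm,
      skeletal_density = skeletal_density,
      deposit_density = deposit_density,
      porosity = porosity, lattice_a_nm = lattice_a_nm
    ),
    class = "pore_network"
  )
}

# Inner (open) body diameters after any deposit shrinkage.
inner_diameters <- function(network) {
  pmax(network$bodies$diameter_nm - 2 * network$bodies$deposit_nm, 0)
}

#' Pore, deposit and skeleton volumes of a network (nm^3)
#'
#' Bookkeeping convention: pore volume is the sum of spherical body volumes
#' (throats carry negligible volume), so deposition conserves
#' skeleton + deposit + pore exactly.
#'
#' @param network A `pore_network`.
#' @return A tibble with one row: pore, deposit, skeleton and interparticle
#'   void volumes in nm^3, plus sample mass in g.
#' @export
network_volumes <- function(network) {
  b <- network$bodies
  intra <- !b$interparticle
  d_in <- inner_diameters(network)
  v_pore <- sum(sphere_volume(d_in[intra]))
  v_initial <- sum(sphere_volume(b$diameter_nm[intra]))
  v_deposit <- v_initial - v_pore
  v_skeleton <- network$domain_size_nm^3 - v_initial
  v_voids <- sum(sphere_volume(b$diameter_nm[!intra]))
  mass_g <- v_skeleton * NM3_TO_ML * network$skeletal_density +
    v_deposit * NM3_TO_ML * network$deposit_density
  tibble::tibble(
    pore_nm3 = v_pore, deposit_nm3 = v_deposit, skeleton_nm3 = v_skeleton,
    interparticle_nm3 = v_voids, sample_mass_g = mass_g
  )
}

# FCC lattice sites in doubled integer coordinates: all (i,j,l) in
# {0,...,2k-1}^3 with even coordinate sum. Real position = coords * a/2.
fcc_sites <- function(k) {
  g <- expand.grid(i = 0:(2 * k - 1), j = 0:(2 * k - 1), l = 0:(2 * k - 1))
  g[(g$i + g$j + g$l) %% 2 == 0, , drop = FALSE]
}

# 12 nearest-neighbour offset vectors of the FCC lattice (doubled coords),
# halved to unordered pairs by keeping lexicographically positive offsets.
FCC_NEIGHBOR_OFFSETS <- local({
  v <- expand.grid(di = -1:1, dj = -1:1, dl = -1:1)
  v <- v[abs(v$di) + abs(v$dj) + abs(v$dl) == 2, ]
  v[v$di > 0 | (v$di == 0 & (v$dj > 0 | (v$dj == 0 & v$dl > 0))), ]
})

#' Generate a synthetic pore network
#'
#' Bodies are spheres on a jittered face-centred-cubic lattice spanning a
#' periodic cubic domain; throats are volume-free cylindrical openings between
#' lattice neighbours. Diameters are drawn log-normally and rescaled by a
#' common factor so that the analytic porosity (sum of sphere volumes minus
#' pairwise lens overlaps) equals `target_porosity`.
#'
#' @param spec A [network_spec()].
#' @return A `pore_network`: tibbles of bodies (positions, diameters, deposit
#'   layers) and throats (body pairs or body-exterior, diameters, blocked
#'   flags), plus domain metadata.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(spec$seed, generate_network_impl(spec))
}

generate_network_impl <- function(spec) {
  med <- spec$body_median_nm
  sdl <- log(spec$body_gsd)
  mean_d3 <- med^3 * exp(4.5 * sdl^2)

  if (is.null(spec$n_bodies)) {
    n_est <- spec$target_porosity * spec$domain_size_nm^3 /
      (pi / 6 * mean_d3) / (1 - spec$core_fraction)
    k <- max(1L, as.integer(round((n_est / 4)^(1 / 3))))
  } else {
    k <- max(1L, as.integer(round((spec$n_bodies / 4)^(1 / 3))))
  }
  a <- spec$domain_size_nm / k

  sites <- fcc_sites(k)
  if (!is.null(spec$n_bodies) && spec$n_bodies < nrow(sites)) {
    sites <- sites[sort(sample(nrow(sites), spec$n_bodies)), , drop = FALSE]
  }
  n_sites <- nrow(sites)
  if (spec$core_fraction > 0) {
    keep <- stats::runif(n_sites) >= spec$core_fraction
    if (!any(keep)) rlang::abort("core_fraction removed every site.")
    sites <- sites[keep, , drop = FALSE]
  }
  n <- nrow(sites)
  pos <- as.matrix(sites) * a / 2
  pos <- pos + matrix(stats::rnorm(3 * n, sd = spec$jitter * a), n, 3)
  pos <- pos %% spec$domain_size_nm

  d <- stats::rlnorm(n, meanlog = log(med), sdlog = sdl)

  # lattice-topology neighbour pairs (periodic)
  twok <- 2L * k
  key <- function(i, j, l) (i %% twok) + (j %% twok) * twok +
    (l %% twok) * twok^2
  site_id <- rep(NA_integer_, twok^3)
  site_id[key(sites$i, sites$j, sites$l) + 1L] <- seq_len(n)
  pairs_from <- integer(0); pairs_to <- integer(0)
  for (r in seq_len(nrow(FCC_NEIGHBOR_OFFSETS))) {
    off <- FCC_NEIGHBOR_OFFSETS[r, ]
    nb <- site_id[key(sites$i + off$di, sites$j + off$dj, sites$l + off$dl) + 1L]
    ok <- !is.na(nb)
    pairs_from <- c(pairs_from, seq_len(n)[ok])
    pairs_to <- c(pairs_to, nb[ok])
  }
  # periodic minimal-image centre distances
  dvec <- pos[pairs_from, , drop = FALSE] - pos[pairs_to, , drop = FALSE]
  L <- spec$domain_size_nm
  dvec <- dvec - round(dvec / L) * L
  r_ij <- sqrt(rowSums(dvec^2))

  # common diameter scale hitting the target porosity, overlap-corrected
  vol_dom <- L^3
  porosity_at <- function(s) {
    (sum(sphere_volume(s * d)) -
       sum(sphere_lens_volume(s * d[pairs_from] / 2, s * d[pairs_to] / 2, r_ij))) /
      vol_dom
  }
  # the lens correction is pairwise-truncated, valid only for shallow
  # overlaps; bracket the root by stepping up from an overlap-free guess
  s0 <- (spec$target_porosity * vol_dom / sum(sphere_volume(d)))^(1 / 3)
  s_lo <- 0.5 * s0
  s_hi <- s_lo
  found <- FALSE
  for (i in 1:40) {
    s_try <- s_hi * 1.06
    if (porosity_at(s_try) >= spec$target_porosity) {
      s_hi <- s_try
      found <- TRUE
      break
    }
    s_lo <- s_hi <- s_try
  }
  if (!found || spec$target_porosity > 0.9) {
    rlang::abort(
      "Requested porosity is infeasible for this domain/diameter combination."
    )
  }
  s <- stats::uniroot(function(x) porosity_at(x) - spec$target_porosity,
                      c(s_lo, s_hi), tol = 1e-10)$root
  d <- s * d
  if (stats::quantile(d, 0.999) > 2 * a) {
    rlang::abort(
      "Requested porosity requires bodies larger than the lattice spacing; enlarge the domain or reduce porosity."
    )
  }

  bodies <- tibble::tibble(
    id = seq_len(n), x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
    diameter_nm = d, deposit_nm = 0, interparticle = FALSE
  )

  # internal throats; dedupe unordered pairs (each appears once by offset
  # construction, but periodic wrap at k=1 can duplicate)
  pr <- cbind(pmin(pairs_from, pairs_to), pmax(pairs_from, pairs_to))
  dup <- duplicated(pr) | pr[, 1] == pr[, 2]
  pr <- pr[!dup, , drop = FALSE]
  throat_d <- spec$throat_to_body_ratio * pmin(d[pr[, 1]], d[pr[, 2]])
  throats <- tibble::tibble(
    from = pr[, 1], to = pr[, 2], diameter_nm = throat_d, blocked = FALSE
  )

  # exterior throats: bodies within one neighbour distance of any domain face
  margin <- a / sqrt(2)
  near_face <- apply(pos, 1, function(p) any(p < margin | p > L - margin))
  ext_ids <- which(near_face)
  if (length(ext_ids) == 0) ext_ids <- which.min(pmin(pos[, 3], L - pos[, 3]))
  if (spec$accessible_fraction < 1) {
    n_keep <- max(1L, floor(spec$accessible_fraction * length(ext_ids)))
    ext_ids <- sort(sample(ext_ids, n_keep))
  }
  exterior <- tibble::tibble(
    from = ext_ids, to = 0L,
    diameter_nm = spec$throat_to_body_ratio * d[ext_ids], blocked = FALSE
  )
  throats <- dplyr::bind_rows(throats, exterior)

  new_pore_network(
    bodies, throats, L, spec$skeletal_density,
    porosity = porosity_at(1), lattice_a_nm = a
  )
}

#' @export
print.pore_network <- function(x, ...) {
  v <- network_volumes(x)
  cat(sprintf(
    "<pore_network> %d bodies, %d throats, domain %.0f nm\n  porosity %.3f, pore volume %.3g mL/g\n",
    nrow(x$bodies), nrow(x$throats), x$domain_size_nm, x$porosity,
    v$pore_nm3 * NM3_TO_ML / v$sample_mass_g
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname generate_network
#' @param x A `pore_network`.
#' @param ... Unused.
#' @method tidy pore_network
#' @export
tidy.pore_network <- function(x, ...) x$bodies

#' @rdname generate_network
#' @method glance pore_network
#' @export
glance.pore_network <- function(x, ...) {
  v <- network_volumes(x)
  tibble::tibble(
    n_bodies = nrow(x$bodies), n_throats = nrow(x$throats),
    porosity = x$porosity,
    pore_volume_mL_per_g = v$pore_nm3 * NM3_TO_ML / v$sample_mass_g,
    mean_body_diameter_nm = mean(inner_diameters(x)[!x$bodies$interparticle]),
    domain_size_nm = x$domain_size_nm
  )
}
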