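#' Describe a loading mode
#'
#' Two geometric emulations of how a dissolved substance ends up in a porous
#' carrier after solvent evaporation: `pore_filling` (the solution penetrates
#' and the solute solidifies as a conformal layer on pore walls, smallest
#' pores closing first, as seen for lipids like DPPC) and `surface_blocking`
#' (the solute precipitates on the particle surface once its solubility limit
#' is reached, occluding pore entrances and creating interparticle voids
#' larger than 500 nm, as seen for proteins like BSA).
#'
#' @param mode `"pore_filling"` or `"surface_blocking"`.
#' @param fill_fraction Fraction in \[0,1\]: of initial pore volume deposited
#'   (`pore_filling`) or of accessible pore volume blocked off
#'   (`surface_blocking`).
#' @param void_median_nm,void_gsd Log-normal parameters of interparticle void
#'   diameters (`surface_blocking` only); draws are truncated above
#'   `void_min_nm`.
#' @param void_min_nm Lower bound for interparticle void diameters (nm).
#' @return A `loading_mode` list.
#' @export
loading_mode <- function(mode = c("pore_filling", "surface_blocking"),
                         fill_fraction,
                         void_median_nm = 800, void_gsd = 1.3,
                         void_min_nm = 500) {
  mode <- match.arg(mode)
  assert_fraction(fill_fraction, "fill_fraction")
  structure(
    list(
      mode = mode, fill_fraction = fill_fraction,
      void_median_nm = void_median_nm, void_gsd = void_gsd,
      void_min_nm = void_min_nm
    ),
    class = "loading_mode"
  )
}

# igraph over bodies (vertices 1..n) plus exterior vertex n+1; edges are
# passable throats (not blocked, diameter above `min_diameter_nm`).
network_graph <- function(network, min_diameter_nm = 0) {
  n <- nrow(network$bodies)
  th <- network$throats
  th <- th[!th$blocked & th$diameter_nm > min_diameter_nm, , drop = FALSE]
  to <- ifelse(th$to == 0L, n + 1L, th$to)
  igraph::graph_from_edgelist(cbind(th$from, to), directed = FALSE) |>
    igraph::add_vertices(max(0L, n + 1L - max(c(th$from, to, 0L))))
}

#' Exterior-accessible pore volume fraction
#'
#' Fraction of intraparticle pore volume reachable from the particle exterior
#' through unblocked throats (graph percolation at zero capillary
#' resistance). This is the volume a porosimeter could ever see.
#'
#' @param network A `pore_network`.
#' @return Scalar fraction in \[0,1\].
#' @export
accessible_volume_fraction <- function(network) {
  n <- nrow(network$bodies)
  g <- network_graph(network)
  comp <- igraph::components(g)$membership
  reach <- comp == comp[n + 1L]
  intra <- !network$bodies$interparticle
  v <- sphere_volume(inner_diameters(network))
  tot <- sum(v[intra])
  if (tot == 0) return(0)
  sum(v[intra & reach[seq_len(n)]]) / tot
}

#' Apply a loading mode to a pore network
#'
#' `pore_filling` grows a conformal deposit layer of uniform thickness on all
#' body and throat walls until the deposited volume reaches
#' `fill_fraction` of the initial pore volume; the smallest pores and throats
#' close first, and skeleton + deposit + remaining pore volume is conserved
#' exactly. `surface_blocking` leaves intraparticle bodies untouched, blocks
#' exterior-adjacent throats until at least `fill_fraction` of the
#' exterior-accessible pore volume is cut off, and appends interparticle
#' voids (> 500 nm) whose total volume equals the displaced solution's worth
#' of material, `fill_fraction` times the initial pore volume.
#'
#' @param network A `pore_network`.
#' @param loading A [loading_mode()].
#' @param seed Integer seed for the (surface-blocking) random choices.
#' @return A modified `pore_network`.
#' @export
apply_loading <- function(network, loading, seed = 1) {
  stopifnot(inherits(network, "pore_network"), inherits(loading, "loading_mode"))
  if (loading$fill_fraction == 0) return(network)
  with_seed(seed, {
    if (loading$mode == "pore_filling") {
      apply_pore_filling(network, loading$fill_fraction)
    } else {
      apply_surface_blocking(network, loading)
    }
  })
}

apply_pore_filling <- function(network, fill) {
  intra <- !network$bodies$interparticle
  d0 <- network$bodies$diameter_nm[intra]
  v0 <- sum(sphere_volume(d0))
  deposited <- function(t) sum(sphere_volume(d0) - sphere_volume(pmax(d0 - 2 * t, 0)))
  if (fill >= 1) {
    t <- max(d0) / 2
  } else {
    t <- stats::uniroot(function(t) deposited(t) - fill * v0,
                        c(0, max(d0) / 2), tol = 1e-13)$root
    # polish: uniroot tolerance is absolute in t; refine for exact volume
    for (i in 1:60) {
      f <- deposited(t) - fill * v0
      slope <- sum(2 * pi * pmax(d0 - 2 * t, 0)^2 / 2) # d(deposited)/dt
      if (slope <= 0 || abs(f) < 1e-12 * v0) break
      t <- t - f / slope
    }
  }
  net <- network
  net$bodies$deposit_nm[intra] <- pmin(t, d0 / 2)
  shrunk <- pmax(net$throats$diameter_nm - 2 * t, 0)
  net$throats$diameter_nm <- shrunk
  net$throats$blocked <- net$throats$blocked | shrunk <= 0
  net
}

apply_surface_blocking <- function(network, loading) {
  net <- network
  n <- nrow(net$bodies)
  v0 <- accessible_volume_fraction(net)
  ext_idx <- which(net$throats$to == 0L & !net$throats$blocked)
  ord <- sample(ext_idx)
  blocked_fraction <- function(m) {
    trial <- net
    trial$throats$blocked[ord[seq_len(m)]] <- TRUE
    (v0 - accessible_volume_fraction(trial)) / v0
  }
  # smallest number of blocked exterior throats reaching the target
  lo <- 0L; hi <- length(ord)
  if (v0 > 0 && loading$fill_fraction > 0) {
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (blocked_fraction(mid) >= loading$fill_fraction) hi <- mid else lo <- mid + 1L
    }
    net$throats$blocked[ord[seq_len(hi)]] <- TRUE
  }

  # interparticle voids: total volume = fill_fraction x initial pore volume
  v_target <- loading$fill_fraction * sum(sphere_volume(net$bodies$diameter_nm[!net$bodies$interparticle]))
  dias <- numeric(0)
  while (sum(sphere_volume(dias)) < v_target) {
    dd <- stats::rlnorm(8, log(loading$void_median_nm), log(loading$void_gsd))
    dias <- c(dias, dd[dd >= loading$void_min_nm])
    if (length(dias) > 1e5) break
  }
  cum <- cumsum(sphere_volume(dias))
  dias <- dias[seq_len(which(cum >= v_target)[1])]
  if (length(dias) > 0) {
    L <- net$domain_size_nm
    voids <- tibble::tibble(
      id = n + seq_along(dias),
      x_nm = stats::runif(length(dias), 0, L),
      y_nm = stats::runif(length(dias), 0, L),
      z_nm = stats::runif(length(dias), 0, L),
      diameter_nm = dias, deposit_nm = 0, interparticle = TRUE
    )
    net$bodies <- dplyr::bind_rows(net$bodies, voids)
    net$throats <- dplyr::bind_rows(
      net$throats,
      tibble::tibble(
        from = voids$id, to = 0L,
        diameter_nm = 0.8 * voids$diameter_nm, blocked = FALSE
      )
    )
  }
  net
}

#' Ground-truth pore size distribution of a network
#'
#' Bins body volumes by their (inner) diameters into a specific-volume
#' histogram, the same currency produced by image analysis and mercury
#' intrusion, so all three can be compared bin-for-bin.
#'
#' @param network A `pore_network`.
#' @param bin_edges Diameter bin edges (nm), e.g. [psd_bin_edges()].
#' @param include_interparticle Include interparticle voids?
#' @return A `pore_psd` tibble (`bin_lo_nm`, `bin_hi_nm`,
#'   `spec_vol_mL_per_g`).
#' @export
network_psd <- function(network, bin_edges = psd_bin_edges(),
                        include_interparticle = TRUE) {
  b <- network$bodies
  keep <- if (include_interparticle) rep(TRUE, nrow(b)) else !b$interparticle
  d <- inner_diameters(network)[keep]
  open <- d > 0
  mass <- network_volumes(network)$sample_mass_g
  bin_volumes(d[open], sphere_volume(d[open]) * NM3_TO_ML / mass, bin_edges)$psd
}
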