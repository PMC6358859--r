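# Independent oracles and small fixtures used across tests. These stay
# deliberately naive (voxel counting, hand-rolled BFS, direct inclusion-
# exclusion) so they never share code paths with the implementation.

# Voxelized porosity of a network: brute-force union of spheres on a
# periodic 3D grid.
voxel_porosity <- function(net, m = 100) {
  L <- net$domain_size_nm
  vox <- L / m
  occ <- array(FALSE, dim = c(m, m, m))
  b <- net$bodies[!net$bodies$interparticle, ]
  d_in <- pmax(b$diameter_nm - 2 * b$deposit_nm, 0)
  for (i in seq_len(nrow(b))) {
    r <- d_in[i] / 2
    if (r <= 0) next
    cc <- c(b$x_nm[i], b$y_nm[i], b$z_nm[i])
    lo <- floor((cc - r) / vox); hi <- ceiling((cc + r) / vox)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    d2 <- outer(outer(((gx + 0.5) * vox - cc[1])^2,
                      ((gy + 0.5) * vox - cc[2])^2, "+"),
                ((gz + 0.5) * vox - cc[3])^2, "+")
    sub <- which(d2 <= r^2, arr.ind = TRUE)
    if (nrow(sub)) {
      occ[cbind((gx[sub[, 1]] %% m) + 1L, (gy[sub[, 2]] %% m) + 1L,
                (gz[sub[, 3]] %% m) + 1L)] <- TRUE
    }
  }
  mean(occ)
}

# Exterior-reachable pore volume fraction by hand-rolled breadth-first
# search (no igraph).
bfs_accessible_fraction <- function(net) {
  b <- net$bodies
  n <- nrow(b)
  th <- net$throats[!net$throats$blocked & net$throats$diameter_nm > 0, ]
  adj <- vector("list", n)
  start <- th$from[th$to == 0L]
  internal <- th[th$to != 0L, ]
  for (r in seq_len(nrow(internal))) {
    i <- internal$from[r]; j <- internal$to[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n)
  queue <- unique(start)
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  d_in <- pmax(b$diameter_nm - 2 * b$deposit_nm, 0)
  v <- pi / 6 * d_in^3
  intra <- !b$interparticle
  sum(v[intra & seen]) / sum(v[intra])
}

# Analytic area fraction of a plane slice through the network: disc areas
# minus pairwise lens overlaps (periodic in-plane). Adequate for dilute
# networks where triple overlaps are negligible.
analytic_slice_porosity <- function(net, offset_nm) {
  L <- net$domain_size_nm
  b <- net$bodies
  r_in <- pmax(b$diameter_nm - 2 * b$deposit_nm, 0) / 2
  dz <- b$z_nm - offset_nm
  dz <- dz - round(dz / L) * L
  hit <- abs(dz) < r_in
  if (!any(hit)) return(0)
  rr <- sqrt(r_in[hit]^2 - dz[hit]^2)
  cx <- b$x_nm[hit]; cy <- b$y_nm[hit]
  area <- sum(pi * rr^2)
  n <- length(rr)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      dx <- cx[(i + 1):n] - cx[i]; dy <- cy[(i + 1):n] - cy[i]
      dx <- dx - round(dx / L) * L; dy <- dy - round(dy / L) * L
      dd <- sqrt(dx^2 + dy^2)
      for (j in seq_along(dd)) {
        r1 <- rr[i]; r2 <- rr[i + j]; d <- dd[j]
        if (d >= r1 + r2) next
        if (d <= abs(r1 - r2)) {
          area <- area - pi * min(r1, r2)^2
        } else {
          a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
          a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
          tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                                   (d - r1 + r2) * (d + r1 + r2)))
          area <- area - (a1 + a2 - tri)
        }
      }
    }
  }
  area / L^2
}

# Hand-built network: n isolated cylindrical pores (throat = body diameter),
# each directly open to the exterior; the no-ink-bottle reference case.
make_cylinder_network <- function(diams, domain_nm = 2000,
                                  skeletal_density = 2.95) {
  n <- length(diams)
  bodies <- tibble::tibble(
    id = seq_len(n),
    x_nm = seq(0.5, n) * domain_nm / (n + 1),
    y_nm = domain_nm / 2, z_nm = domain_nm / 2,
    diameter_nm = diams, deposit_nm = 0, interparticle = FALSE
  )
  throats <- tibble::tibble(
    from = seq_len(n), to = 0L, diameter_nm = diams, blocked = FALSE
  )
  poreload:::new_pore_network(
    bodies, throats, domain_nm, skeletal_density,
    porosity = sum(pi / 6 * diams^3) / domain_nm^3, lattice_a_nm = NA_real_
  )
}

# One 200 nm body behind a single 40 nm throat: the canonical ink bottle.
make_ink_bottle <- function(body_nm = 200, throat_nm = 40) {
  bodies <- tibble::tibble(
    id = 1L, x_nm = 500, y_nm = 500, z_nm = 500,
    diameter_nm = body_nm, deposit_nm = 0, interparticle = FALSE
  )
  throats <- tibble::tibble(
    from = 1L, to = 0L, diameter_nm = throat_nm, blocked = FALSE
  )
  poreload:::new_pore_network(
    bodies, throats, 1000, 2.95,
    porosity = pi / 6 * body_nm^3 / 1000^3, lattice_a_nm = NA_real_
  )
}

# Table of loading-solution properties used in the wetting analyses
# (density kg/m^3, viscosity mPa s, surface tension mN/m, contact angle deg).
loading_solutions <- function() {
  tibble::tibble(
    label = c("methanol_dppc_high", "methanol_dppc_medium",
              "methanol_dppc_low", "water_bsa_high", "water_bsa_medium",
              "water_bsa_low"),
    density = c(789.0, 790.9, 785.6, 1001.7, 1002.0, 999.1),
    viscosity = c(0.59, 0.57, 0.54, 0.82, 0.75, 0.69),
    surface_tension = c(22.0, 21.9, 21.8, 47.5, 48.7, 50.8),
    contact_angle = c(45.3, 24.2, 34.9, 53.4, 39.8, 66.3)
  )
}
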