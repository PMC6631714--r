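# Key-atom selection: per-atom solvent-accessible surface area on the
# ligand-free site, then a 4-A expansion around the overlaid ligands with a
# >5% exposure filter.

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is probed on a sphere of radius `r_vdw + probe_radius` sampled
#' with a deterministic Fibonacci lattice; a point is accessible if it lies
#' outside every other atom's probe-expanded sphere.  The exposed fraction
#' uses the probe-expanded sphere as denominator, so it equals the
#' accessible solid-angle fraction regardless of atom radius.
#'
#' @param site a [site_model()] (ligand-free).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960, >= 60).
#' @return list of class `SasaResult` with `area` (A^2) and
#'   `exposed_fraction` per atom.
#' @export
shrake_rupley_sasa <- function(site, probe_radius = 1.4, n_points = 960) {
  if (n_points < 60) stopf("n_points must be >= 60")
  if (probe_radius <= 0) stopf("probe_radius must be > 0")
  atoms <- site$atoms
  n <- nrow(atoms)
  xyz <- atom_coords(atoms)
  rads <- atoms$vdw_radius + probe_radius
  sphere <- fibonacci_sphere(n_points)
  area <- numeric(n)
  frac <- numeric(n)
  # neighbor prescreen: only atoms whose expanded spheres can overlap matter
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rads[i], 2, xyz[i, ], "+")
    nb <- which(d2[i, ] <= (rads[i] + rads)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- cross_dist2(pts[acc, , drop = FALSE], xyz[j, , drop = FALSE])
      buried <- dj[, 1] < rads[j]^2
      acc[which(acc)[buried]] <- FALSE
    }
    frac[i] <- sum(acc) / n_points
    area[i] <- frac[i] * 4 * pi * rads[i]^2
  }
  structure(list(area = area, exposed_fraction = frac,
                 probe_radius = probe_radius, n_points = n_points),
            class = "SasaResult")
}

#' Select the CF key atoms of a site
#'
#' Key atoms are site atoms within `expansion` (closed cutoff, <=) of any
#' atom of any overlaid ligand coordinate set AND exposing strictly more
#' than `min_exposed_fraction` of their surface to the solvent on the
#' ligand-free site.  The resulting index list is ordered by ascending atom
#' index and frozen: it defines the CF slot order.
#'
#' @param site a [site_model()].
#' @param ligand_coord_sets list of n_i x 3 coordinate matrices of overlaid
#'   ligands (site frame).
#' @param expansion distance cutoff around ligand atoms, Angstrom.
#' @param min_exposed_fraction exposure threshold (strict, "more than").
#' @param sasa optional precomputed [shrake_rupley_sasa()] result.
#' @param probe_radius,n_points forwarded to the SASA computation.
#' @return the site with `key_atom_indices` filled in.
#' @export
select_key_atoms <- function(site, ligand_coord_sets, expansion = 4.0,
                             min_exposed_fraction = 0.05, sasa = NULL,
                             probe_radius = 1.4, n_points = 960) {
  if (!length(ligand_coord_sets)) stopf("no ligand coordinate sets: nothing to expand from")
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(site, probe_radius, n_points)
  xyz <- atom_coords(site$atoms)
  lig <- do.call(rbind, lapply(ligand_coord_sets, function(m) matrix(m, ncol = 3)))
  d2 <- cross_dist2(xyz, lig)
  near <- apply(d2, 1, min) <= expansion^2
  exposed <- sasa$exposed_fraction > min_exposed_fraction
  site$key_atom_indices <- which(near & exposed)
  site$sasa <- sasa
  site
}
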