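# Domain types: atoms, sites, ligands, poses, pose pools.
#
# Atoms are stored as plain data frames (one row per atom) with the columns
# element, x, y, z, partial_charge, formal_charge, vdw_radius, is_hbd, is_hba.
# All atom indices in this package are 1-based.

# Bondi van der Waals radii (Angstrom), H at 1.2.
.BONDI <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90
)
.DEFAULT_RADIUS <- 1.70

#' Bondi van der Waals radius of an element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom (1.2 for H; unknown elements
#'   fall back to 1.70 with a warning).
#' @export
vdw_radius <- function(element) {
  r <- unname(.BONDI[element])
  if (anyNA(r)) {
    warnf("unknown element(s) %s: using default vdW radius %.2f",
          paste(unique(element[is.na(r)]), collapse = ","), .DEFAULT_RADIUS)
    r[is.na(r)] <- .DEFAULT_RADIUS
  }
  r
}

#' Build an atom table
#'
#' @param element character vector of element symbols.
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param partial_charge numeric vector (elementary charge units), default 0.
#' @param formal_charge integer vector, default 0.
#' @param name optional atom names.
#' @return data.frame of atoms with radii assigned and H-bond roles unset.
#' @export
atom_table <- function(element, coords, partial_charge = 0, formal_charge = 0L,
                       name = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(element)
  stopifnot(nrow(coords) == n)
  if (!all(is.finite(coords))) stopf("atom coordinates must be finite")
  df <- data.frame(
    element = as.character(element),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    partial_charge = rep_len(as.numeric(partial_charge), n),
    formal_charge = rep_len(as.integer(formal_charge), n),
    stringsAsFactors = FALSE
  )
  df$vdw_radius <- vdw_radius(df$element)
  df$is_hbd <- FALSE
  df$is_hba <- FALSE
  df$name <- if (is.null(name)) paste0(df$element, seq_len(n)) else as.character(name)
  df
}

atom_coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Assign hydrogen-bond donor/acceptor roles
#'
#' Donor flag goes on each H bonded to N, O or S.  Acceptor flag goes on any
#' O or N with formal charge <= 0, excluding N that carries an H (amide-like
#' N-H nitrogens are treated as donors-only).  When no bond list is given,
#' bonds to H are inferred from distance (H within `h_bond_length` of an
#' N/O/S heavy atom).
#'
#' @param atoms atom table.
#' @param bonds optional data.frame with columns i, j (1-based atom indices).
#' @param h_bond_length covalent H-X distance cutoff in Angstrom for bond
#'   inference (default 1.25).
#' @return atom table with `is_hbd`/`is_hba` filled in.
#' @export
assign_hbond_roles <- function(atoms, bonds = NULL, h_bond_length = 1.25) {
  n <- nrow(atoms)
  el <- atoms$element
  heavy_don <- el %in% c("N", "O", "S")
  h_partner <- rep(FALSE, n)   # H atoms bonded to N/O/S
  n_with_h <- rep(FALSE, n)    # N atoms carrying an H
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      if (el[i] == "H" && heavy_don[j]) h_partner[i] <- TRUE
      if (el[j] == "H" && heavy_don[i]) h_partner[j] <- TRUE
      if (el[i] == "H" && el[j] == "N") n_with_h[j] <- TRUE
      if (el[j] == "H" && el[i] == "N") n_with_h[i] <- TRUE
    }
  } else if (any(el == "H") && any(heavy_don)) {
    xyz <- atom_coords(atoms)
    d2 <- cross_dist2(xyz[el == "H", , drop = FALSE],
                      xyz[heavy_don, , drop = FALSE])
    near <- d2 <= h_bond_length^2
    h_partner[el == "H"] <- apply(near, 1, any)
    don_idx <- which(heavy_don)
    for (k in seq_len(nrow(near))) {
      hit <- don_idx[near[k, ]]
      n_with_h[hit[el[hit] == "N"]] <- TRUE
    }
  }
  atoms$is_hbd <- h_partner
  atoms$is_hba <- (el == "O" & atoms$formal_charge <= 0) |
    (el == "N" & atoms$formal_charge <= 0 & !n_with_h)
  atoms
}

#' Construct a SiteModel
#'
#' A rigid protein site: typed fixed atoms plus the ordered list of key
#' contact atoms that defines the CF slot order.  `key_atom_indices` is
#' frozen once set.
#'
#' @param atoms atom table.
#' @param key_atom_indices ordered integer vector of 1-based atom indices.
#' @param hot_spots optional atom indices (metadata only).
#' @param provenance named list recording input source and charge assignment.
#' @return object of class `SiteModel`.
#' @export
site_model <- function(atoms, key_atom_indices = integer(0), hot_spots = NULL,
                       provenance = list()) {
  key_atom_indices <- as.integer(key_atom_indices)
  if (anyDuplicated(key_atom_indices)) stopf("key_atom_indices must be unique")
  if (length(key_atom_indices) &&
      (min(key_atom_indices) < 1 || max(key_atom_indices) > nrow(atoms)))
    stopf("key_atom_indices out of range")
  structure(list(atoms = atoms, key_atom_indices = key_atom_indices,
                 hot_spots = hot_spots, provenance = provenance),
            class = "SiteModel")
}

#' @export
print.SiteModel <- function(x, ...) {
  cat(sprintf("SiteModel: %d atoms, %d key atoms, %d hot spots\n",
              nrow(x$atoms), length(x$key_atom_indices),
              length(x$hot_spots)))
  invisible(x)
}

#' Construct a Ligand
#'
#' @param ligand_id string identifier.
#' @param atoms atom table.
#' @param bonds data.frame with columns i, j, order (1-based indices).
#' @return object of class `Ligand`.  Warns (does not fail) if the bond
#'   graph is disconnected.
#' @export
ligand <- function(ligand_id, atoms, bonds) {
  n <- nrow(atoms)
  if (nrow(bonds) > 0 &&
      (min(bonds$i, bonds$j) < 1 || max(bonds$i, bonds$j) > n))
    stopf("ligand '%s': bond indices out of range", ligand_id)
  # connectivity check by BFS over the bond graph
  if (n > 1) {
    adj <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
      adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
    }
    seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen))
      warnf("ligand '%s': bond graph is disconnected (%d components reachable check failed)",
            ligand_id, sum(!seen))
  }
  structure(list(ligand_id = ligand_id, atoms = atoms, bonds = bonds),
            class = "Ligand")
}

#' Construct a Pose
#'
#' One ligand conformer in the shared site frame.
#'
#' @param ligand_id,conformer_id identifiers.
#' @param coords n x 3 coordinate matrix, Angstrom, site frame.
#' @param energy pose energy, kcal/mol.
#' @param run_id docking-run identifier.
#' @param rmsd_to_native optional RMSD to the native pose, Angstrom.
#' @return object of class `Pose`.
#' @export
pose <- function(ligand_id, conformer_id, coords, energy, run_id = "run1",
                 rmsd_to_native = NA_real_) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (!is.finite(energy)) stopf("pose '%s': energy must be finite", conformer_id)
  structure(list(ligand_id = ligand_id, conformer_id = as.character(conformer_id),
                 coords = coords, energy = as.numeric(energy),
                 run_id = run_id, rmsd_to_native = rmsd_to_native),
            class = "Pose")
}

#' Construct a PosePool
#'
#' @param poses list of [pose()] objects sharing one ligand and atom count.
#' @return object of class `PosePool` with cached minimum energy.
#' @export
pose_pool <- function(poses) {
  if (!length(poses)) stopf("pose pool must contain at least one pose")
  ids <- vapply(poses, function(p) p$ligand_id, "")
  if (length(unique(ids)) != 1) stopf("all poses in a pool must share ligand_id")
  nat <- vapply(poses, function(p) nrow(p$coords), 0L)
  if (length(unique(nat)) != 1)
    stopf("pose atom counts differ within pool of ligand '%s'", ids[1])
  structure(list(ligand_id = ids[1], poses = poses,
                 min_energy = min(vapply(poses, function(p) p$energy, 0))),
            class = "PosePool")
}

#' @export
print.PosePool <- function(x, ...) {
  cat(sprintf("PosePool '%s': %d poses, min energy %.3f kcal/mol\n",
              x$ligand_id, length(x$poses), x$min_energy))
  invisible(x)
}

pool_energies <- function(pool) vapply(pool$poses, function(p) p$energy, 0)
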