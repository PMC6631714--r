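# Site-anchored fuzzy Contact Fingerprints.
#
# For each key atom of the site, two fuzzy contact lists are built over the
# ligand atoms of a pose: "direct" (distance cutoff = sum of vdW radii plus
# a 0.5-A tolerance) and "long-range" (direct cutoff plus a water radius,
# extending the direct list by putative water-displacing contacts).  A
# ligand atom's association score to a list is a sigmoid of its distance
# with inflexion at the cutoff.  Each list yields five channels per key
# atom: total contacts, H-bond donors, H-bond acceptors, summed partial
# charge, summed absolute partial charge, all weighted by the scores.

.CF_CHANNELS <- c("n_contacts", "n_hbd", "n_hba", "sum_charge", "sum_abs_charge")
.CF_RANGES <- c("direct", "long_range")

#' Contact Fingerprint slot schema
#'
#' Slot order is key-atom major, then range (direct, long_range), then
#' channel; vector length is `|key atoms| * 2 * 5`.
#'
#' @param key_atom_indices ordered 1-based site atom indices.
#' @return object of class `CFSchema` with precomputed slot names.
#' @export
cf_schema <- function(key_atom_indices) {
  key_atom_indices <- as.integer(key_atom_indices)
  if (!length(key_atom_indices)) stopf("schema needs at least one key atom")
  if (anyDuplicated(key_atom_indices)) stopf("key atoms must be unique")
  slots <- as.vector(t(outer(key_atom_indices, paste(rep(.CF_RANGES, each = 5),
                             rep(.CF_CHANNELS, 2), sep = "_"),
                             function(a, rc) paste0("a", a, "_", rc))))
  structure(list(key_atom_indices = key_atom_indices,
                 channels = .CF_CHANNELS, ranges = .CF_RANGES,
                 slot_names = slots,
                 length = length(key_atom_indices) * 10L),
            class = "CFSchema")
}

#' Fuzzy contact association score
#'
#' `1 / (1 + exp(steepness * (distance - cutoff)))`: 1 well inside the
#' cutoff, 0.5 at the cutoff, 0 far outside; strictly decreasing.
#'
#' @param distance interatomic distance, Angstrom (>= 0).
#' @param cutoff inflexion point, Angstrom (> 0).
#' @param steepness sigmoid slope, 1/Angstrom (> 0).
#' @return score in (0, 1).
#' @export
contact_score <- function(distance, cutoff, steepness = 5) {
  if (any(distance < 0)) stopf("distance must be non-negative")
  if (any(cutoff <= 0) || steepness <= 0) stopf("cutoff and steepness must be > 0")
  1 / (1 + exp(steepness * (distance - cutoff)))
}

#' Compute the Contact Fingerprint of one pose
#'
#' @param pose a [pose()] in the site frame.
#' @param lig the [ligand()] carrying atom properties (radii, charges,
#'   H-bond roles); hydrogens participate as contact atoms.
#' @param site the [site_model()].
#' @param schema a [cf_schema()] whose key atoms exist in the site.
#' @param tolerance added to the vdW-radii sum for the direct cutoff (A).
#' @param water_radius added to the direct cutoff for the long-range band (A).
#' @param steepness sigmoid slope (1/A).
#' @return named numeric vector of class `CFVector` (attributes: schema,
#'   ligand_id, conformer_id).
#' @export
compute_cf <- function(pose, lig, site, schema, tolerance = 0.5,
                       water_radius = 1.4, steepness = 5) {
  if (max(schema$key_atom_indices) > nrow(site$atoms))
    stopf("schema key atoms not present in site (%d atoms)", nrow(site$atoms))
  if (nrow(pose$coords) != nrow(lig$atoms))
    stopf("pose/ligand atom count mismatch")
  site_xyz <- atom_coords(site$atoms)[schema$key_atom_indices, , drop = FALSE]
  r_site <- site$atoms$vdw_radius[schema$key_atom_indices]
  d <- sqrt(cross_dist2(site_xyz, pose$coords))       # k x n
  cut_direct <- outer(r_site, lig$atoms$vdw_radius, "+") + tolerance
  Sd <- 1 / (1 + exp(steepness * (d - cut_direct)))
  Sl <- 1 / (1 + exp(steepness * (d - (cut_direct + water_radius))))
  q <- lig$atoms$partial_charge
  channels <- function(S) cbind(rowSums(S),
                                S %*% lig$atoms$is_hbd,
                                S %*% lig$atoms$is_hba,
                                S %*% q,
                                S %*% abs(q))
  # interleave: per key atom, direct channels then long-range channels
  v <- as.vector(t(cbind(channels(Sd), channels(Sl))))
  names(v) <- schema$slot_names
  structure(v, class = "CFVector", schema = schema,
            ligand_id = pose$ligand_id, conformer_id = pose$conformer_id)
}

#' Contact Fingerprint matrix of a pose ensemble
#'
#' @param pool a [pose_pool()] or list of poses.
#' @param lig,site,schema,... forwarded to [compute_cf()].
#' @return N x L numeric matrix (rownames conformer ids, colnames slot names).
#' @export
cf_matrix <- function(pool, lig, site, schema, ...) {
  poses <- if (inherits(pool, "PosePool")) pool$poses else pool
  X <- t(vapply(poses, function(p) as.numeric(compute_cf(p, lig, site, schema, ...)),
                numeric(schema$length)))
  rownames(X) <- vapply(poses, function(p) p$conformer_id, "")
  colnames(X) <- schema$slot_names
  X
}

#' Query one CF slot
#'
#' Returns the named slot's value.  Single-key-atom contact intensities (the
#' carbonyl-O / amide-H counts behind the LeuO / LeuNH screening baselines)
#' are slot lookups; their product (`LeuTot`-style) is
#' [hotspot_contact_product()].
#'
#' @param cf a [compute_cf()] vector or one row of [cf_matrix()] with names.
#' @param key_atom 1-based site atom index.
#' @param range `"direct"` or `"long_range"`.
#' @param channel one of `n_contacts, n_hbd, n_hba, sum_charge, sum_abs_charge`.
#' @return the slot value.
#' @export
contact_intensity <- function(cf, key_atom, range = "direct",
                              channel = "n_contacts") {
  slot <- paste0("a", key_atom, "_", range, "_", channel)
  nm <- names(cf)
  if (is.null(nm)) {
    sc <- attr(cf, "schema")
    if (is.null(sc)) stopf("CF vector carries no slot names")
    nm <- sc$slot_names
  }
  hit <- match(slot, nm)
  if (is.na(hit)) {
    atoms <- unique(sub("^a([0-9]+)_.*$", "\\1", nm))
    stopf("unknown slot '%s'; valid key atoms: %s; ranges: %s; channels: %s",
          slot, paste(atoms, collapse = ","), paste(.CF_RANGES, collapse = ","),
          paste(.CF_CHANNELS, collapse = ","))
  }
  unname(cf[[hit]])
}

#' Product of direct contact counts at two hot-spot atoms
#'
#' Marks how often ligand atoms sit in the neighborhood of both site key
#' spots simultaneously (the `LeuTot`-style baseline = LeuO x LeuNH).
#'
#' @param cf CF vector.
#' @param key_atom_1,key_atom_2 1-based site atom indices of the two spots.
#' @return the product of the two direct `n_contacts` slots.
#' @export
hotspot_contact_product <- function(cf, key_atom_1, key_atom_2) {
  contact_intensity(cf, key_atom_1, "direct", "n_contacts") *
    contact_intensity(cf, key_atom_2, "direct", "n_contacts")
}
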