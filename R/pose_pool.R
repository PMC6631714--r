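# Pose-ensemble bookkeeping: energy window, diverse-subset selection,
# energy convergence criterion, capped RMSD, docking score.

#' Energy-window filter
#'
#' Keeps poses whose excess energy over the pool minimum does not exceed
#' `window` (strictly larger excess discards; the boundary pose is kept).
#' Pose order is preserved.
#'
#' @param pool a [pose_pool()].
#' @param window energy window, kcal/mol (default 50).
#' @return filtered [pose_pool()].
#' @export
energy_window_filter <- function(pool, window = 50) {
  e <- pool_energies(pool)
  keep <- e <= min(e) + window
  pose_pool(pool$poses[keep])
}

#' Greedy diverse-subset selection
#'
#' Iteratively accepts the energetically best remaining pose, then discards
#' every pose within `threshold` of an accepted one, until `n` poses are
#' accepted or the list is exhausted.  Energy ties break by lexicographic
#' conformer id, making the selection deterministic.
#'
#' @param pool a [pose_pool()].
#' @param n target subset size (default 200).
#' @param dissimilarity function(pose_a, pose_b) -> dissimilarity, or a
#'   precomputed symmetric matrix in pool order.  The default is the
#'   Euclidean distance between pose coordinate matrices, a stand-in for a
#'   descriptor-space distance; pass CF-based distances for descriptor-aware
#'   selection.
#' @param threshold poses closer than this to an accepted pose are discarded.
#' @return [pose_pool()] of the accepted poses, in acceptance order.
#' @export
select_diverse <- function(pool, n = 200, dissimilarity = NULL, threshold = 1.0) {
  if (n <= 0) stopf("n must be positive")
  poses <- pool$poses
  e <- pool_energies(pool)
  cid <- vapply(poses, function(p) p$conformer_id, "")
  ord <- order(e, cid)
  if (is.matrix(dissimilarity)) {
    D <- dissimilarity
  } else {
    f <- if (is.null(dissimilarity))
      function(a, b) sqrt(mean((a$coords - b$coords)^2)) else dissimilarity
    D <- NULL
  }
  accepted <- integer(0)
  alive <- rep(TRUE, length(poses))
  for (i in ord) {
    if (!alive[i]) next
    accepted <- c(accepted, i)
    if (length(accepted) >= n) break
    d_i <- if (!is.null(D)) D[i, ] else
      vapply(poses, function(p) f(poses[[i]], p), 0)
    alive[d_i <= threshold] <- FALSE
  }
  pose_pool(poses[accepted])
}

#' Energy Convergence Criterion
#'
#' Fulfilled when at least five simulations have been run and the
#' simulations ranked 2-5 by their minimum energy all lie within `window`
#' of the best minimum.
#'
#' @param minima per-simulation minimum energies, kcal/mol.
#' @param window agreement window, kcal/mol (default 1).
#' @param required_count simulations that must agree (default 5).
#' @return logical.
#' @export
ecc_fulfilled <- function(minima, window = 1.0, required_count = 5) {
  if (window <= 0) stopf("window must be > 0")
  if (!length(minima)) stopf("at least one simulation required")
  if (length(minima) < required_count) return(FALSE)
  s <- sort(minima)
  all(s[2:required_count] <= s[1] + window)
}

#' Run simulations until the ECC is met
#'
#' Book-keeping helper: calls `simulate(i)` (returning a minimum energy) up
#' to `max_simulations` times, stopping early once [ecc_fulfilled()].
#'
#' @param simulate function(i) -> minimum energy of run i.
#' @param window,required_count as in [ecc_fulfilled()].
#' @param max_simulations repeat cap (default 20).
#' @return list with `minima`, `n_simulations`, `converged`.
#' @export
run_until_ecc <- function(simulate, window = 1.0, required_count = 5,
                          max_simulations = 20) {
  minima <- numeric(0)
  for (i in seq_len(max_simulations)) {
    minima <- c(minima, simulate(i))
    if (ecc_fulfilled(minima, window, required_count)) break
  }
  list(minima = minima, n_simulations = length(minima),
       converged = ecc_fulfilled(minima, window, required_count))
}

#' Heavy-atom RMSD between two poses of one ligand
#'
#' Index-matched, computed in the shared site frame with no superposition.
#' Optionally capped (values above `cap` set to `cap`, the convention used
#' before landscape modeling so that quasi-undocked poses do not dominate).
#'
#' @param p a [pose()].
#' @param native the reference [pose()], same ligand and atom order.
#' @param lig optional [ligand()]; when given, hydrogens are excluded.
#' @param cap cap in Angstrom, or `NULL` for the raw value.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(p, native, lig = NULL, cap = NULL) {
  if (nrow(p$coords) != nrow(native$coords))
    stopf("atom count mismatch: %d vs %d", nrow(p$coords), nrow(native$coords))
  sel <- if (!is.null(lig)) lig$atoms$element != "H" else
    rep(TRUE, nrow(p$coords))
  d2 <- rowSums((p$coords[sel, , drop = FALSE] -
                 native$coords[sel, , drop = FALSE])^2)
  r <- sqrt(mean(d2))
  if (!is.null(cap)) min(r, cap) else r
}

#' Label poses as native-like
#'
#' Strict threshold: RMSD < 2.0 A.
#'
#' @param rmsd numeric vector of RMSD values, Angstrom.
#' @param threshold native-like threshold (default 2.0).
#' @return logical vector.
#' @export
is_native_like <- function(rmsd, threshold = 2.0) rmsd < threshold

#' Docking score
#'
#' Difference between the most stable bound pose and the most stable free
#' ligand geometry: `dE = min E(bound) - min E(free)`.
#'
#' @param bound_pool,free_pool non-empty [pose_pool()]s (or numeric energy
#'   vectors).
#' @return dE in kcal/mol.
#' @export
docking_score <- function(bound_pool, free_pool) {
  eb <- if (inherits(bound_pool, "PosePool")) pool_energies(bound_pool) else bound_pool
  ef <- if (inherits(free_pool, "PosePool")) pool_energies(free_pool) else free_pool
  if (!length(eb) || !length(ef)) stopf("both pools must be non-empty")
  min(eb) - min(ef)
}
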