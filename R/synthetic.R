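# Synthetic fixture generators: a toy binding site with two hot-spot atoms
# (a carbonyl-O / amide-H pair mimicking the key bidentate anchor of kinase
# sites), pose ensembles with controlled RMSD and funnel-shaped energies,
# paired run A/run B ensembles with controlled conformational-space overlap,
# and compound sets whose pK correlates with the hot-spot contact pattern.
# Everything is seed-deterministic and writes/reads standard formats.

#' Parameters of the synthetic generators
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param n_site_atoms shell atoms of the toy site (a far rim of
#'   `n_rim_atoms` more is added outside the key-atom expansion range).
#' @param n_rim_atoms far-rim atoms (never key atoms).
#' @param n_poses poses per generated ensemble.
#' @param e0 funnel energy floor, kcal/mol.
#' @param funnel_slope a in `E = e0 + a * RMSD + noise`, kcal/mol per A.
#' @param funnel_noise noise SD sigma, kcal/mol.
#' @param native_fraction target fraction of native-like (< 2 A) poses.
#' @param max_rmsd upper edge of the non-native RMSD band, A.
#' @param mode_offset displacement of conformational-space modes from the
#'   native pose in paired runs, A.
#' @param mode_jitter within-mode positional jitter SD, A.
#' @param n_modes modes per run in paired ensembles.
#' @param n_top,n_weak,n_decoy screening-set class counts (mirroring a
#'   100 / 91 / 101 potent / weak / decoy composition).
#' @param n_poses_per_compound docked poses per screening compound.
#' @param effect_size strength of the pK / hot-spot-contact coupling
#'   (0 = none).
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1, n_site_atoms = 80, n_rim_atoms = 20,
                           n_poses = 200, e0 = -50, funnel_slope = 2,
                           funnel_noise = 1, native_fraction = 0.2,
                           max_rmsd = 8, mode_offset = 3.0, mode_jitter = 0.5,
                           n_modes = 4, n_top = 100, n_weak = 91,
                           n_decoy = 101, n_poses_per_compound = 8,
                           effect_size = 0.8) {
  stopifnot(n_site_atoms > 0, n_poses > 0, funnel_noise >= 0,
            native_fraction >= 0, native_fraction <= 1)
  structure(list(seed = as.integer(seed), n_site_atoms = n_site_atoms,
                 n_rim_atoms = n_rim_atoms, n_poses = n_poses, e0 = e0,
                 funnel_slope = funnel_slope, funnel_noise = funnel_noise,
                 native_fraction = native_fraction, max_rmsd = max_rmsd,
                 mode_offset = mode_offset, mode_jitter = mode_jitter,
                 n_modes = n_modes, n_top = n_top, n_weak = n_weak,
                 n_decoy = n_decoy,
                 n_poses_per_compound = n_poses_per_compound,
                 effect_size = effect_size),
            class = "SyntheticSpec")
}

toy_ligand <- function() {
  el <- c("C", "C", "C", "O", "N", "H", "H", "C")
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 0, 1.2),
               c(1.5, 0, 1.4), c(1.5, 0, 2.4), c(2.2, 0.8, -0.4),
               c(-2.6, 1.0, 0))
  q <- c(0.40, 0.05, 0.00, -0.50, -0.40, 0.35, 0.05, 0.05)
  bonds <- data.frame(i = c(1, 1, 1, 2, 5, 2, 3),
                      j = c(2, 3, 4, 5, 6, 7, 8),
                      order = c(1, 1, 2, 1, 1, 1, 1))
  atoms <- assign_hbond_roles(atom_table(el, xyz, q), bonds)
  ligand("toy", atoms, bonds)
}

#' Build the toy site, ligand and native pose
#'
#' A spherical shell of typed atoms around a cavity holding the ligand,
#' with two designated hot-spot atoms (a carbonyl-like O facing the
#' ligand's donor H, an amide-like H facing the ligand's acceptor O) and a
#' far rim of atoms outside the key-atom expansion range.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `site`, `ligand`, `native` pose, `hotspot_o`, `hotspot_h`
#'   (site atom indices).
#' @export
make_toy_site <- function(spec = synthetic_spec()) {
  lig <- toy_ligand()
  lig_xyz <- atom_coords(lig$atoms)
  with_seed(derive_seed(spec$seed, "toy_site"), {
    # hot spots: carbonyl O 1.9 A above the ligand donor H, amide H (with
    # its N) 1.9 A above the ligand acceptor O
    hot <- rbind(c(1.5, 0, 4.3),    # O, faces ligand H6
                 c(0, 0, 3.1),      # H, faces ligand O4
                 c(0, 0, 4.1))      # N carrying that H
    hot_el <- c("O", "H", "N")
    hot_q <- c(-0.55, 0.30, -0.40)
    ctr <- c(0, 0, 0.8)
    shell <- sweep(fibonacci_sphere(spec$n_site_atoms) * 5.0, 2, ctr, "+")
    shell <- shell + matrix(stats::rnorm(length(shell), sd = 0.15),
                            ncol = 3)
    keep <- rep(TRUE, nrow(shell))
    d_lig <- sqrt(cross_dist2(shell, lig_xyz))
    d_hot <- sqrt(cross_dist2(shell, hot))
    keep <- apply(d_lig, 1, min) > 3.0 & apply(d_hot, 1, min) > 2.8
    shell <- shell[keep, , drop = FALSE]
    rim <- sweep(fibonacci_sphere(spec$n_rim_atoms) * 11.0, 2, ctr, "+")
    els <- rep(c("C", "C", "N", "C", "O", "C"), length.out = nrow(shell))
    qs <- c(C = 0.05, N = -0.35, O = -0.45)[els] +
      stats::rnorm(nrow(shell), sd = 0.02)
    xyz <- rbind(hot, shell, rim)
    el <- c(hot_el, els, rep("C", nrow(rim)))
    q <- round(c(hot_q, qs, rep(0.05, nrow(rim))), 4)
    atoms <- assign_hbond_roles(atom_table(el, xyz, q))
    site <- site_model(atoms, hot_spots = c(1L, 2L),
                       provenance = list(source = "synthetic",
                                         seed = spec$seed))
    native <- pose("toy", "toy_native", lig_xyz, energy = spec$e0,
                   run_id = "native", rmsd_to_native = 0)
    list(site = site, ligand = lig, native = native,
         hotspot_o = 1L, hotspot_h = 2L)
  })
}

random_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a pose ensemble with controlled RMSD and funnel energies
#'
#' Poses are rigid displacements of the native pose: with probability
#' `native_fraction` the displacement is drawn in the native-like band
#' (0.2-1.9 A), otherwise in (2.1, `max_rmsd`).  A rigid translation of
#' magnitude t has RMSD exactly t, so the true RMSD is stored with each
#' pose.  Energies follow the funnel `E = e0 + a * RMSD + N(0, sigma^2)`.
#'
#' @param spec a [synthetic_spec()].
#' @param native the native [pose()].
#' @param run_id run identifier.
#' @param seed_name substream name (vary to get independent ensembles).
#' @return a [pose_pool()] with `rmsd_to_native` filled in.
#' @export
make_pose_ensemble <- function(spec, native, run_id = "run1",
                               seed_name = run_id) {
  with_seed(derive_seed(spec$seed, paste0("ensemble_", seed_name)), {
    n <- spec$n_poses
    nat <- stats::runif(n) < spec$native_fraction
    t <- ifelse(nat, stats::runif(n, 0.2, 1.9),
                stats::runif(n, 2.1, spec$max_rmsd))
    u <- random_unit(n)
    e <- spec$e0 + spec$funnel_slope * t +
      stats::rnorm(n, sd = spec$funnel_noise)
    poses <- lapply(seq_len(n), function(i)
      pose(native$ligand_id, sprintf("%s_p%04d", run_id, i),
           sweep(native$coords, 2, t[i] * u[i, ], "+"),
           energy = e[i], run_id = run_id, rmsd_to_native = t[i]))
    pose_pool(poses)
  })
}

#' Generate paired run A / run B ensembles with controlled overlap
#'
#' Each run samples poses around `n_modes` conformational-space modes
#' (well-separated rigid displacements of the native pose).  The two runs
#' share `round(overlap * n_modes)` modes: `overlap = 1` makes them
#' statistically identical, `overlap = 0` disjoint.
#'
#' @param spec a [synthetic_spec()].
#' @param overlap shared-mode fraction in `[0, 1]`.
#' @param toy optional [make_toy_site()] output (rebuilt otherwise).
#' @return list: `run_a`, `run_b` ([pose_pool()]s), `toy`, `modes`,
#'   `modes_a`, `modes_b` (mode indices).
#' @export
make_paired_runs <- function(spec, overlap = 1, toy = NULL) {
  if (overlap < 0 || overlap > 1) stopf("overlap must lie in [0, 1]")
  if (is.null(toy)) toy <- make_toy_site(spec)
  native <- toy$native
  m <- spec$n_modes
  shared <- round(overlap * m)
  modes <- fibonacci_sphere(2 * m - shared) * spec$mode_offset
  idx_a <- seq_len(m)
  idx_b <- as.integer(seq_len(m) + (m - shared))
  gen <- function(run_id, idx) {
    with_seed(derive_seed(spec$seed, paste0("paired_", run_id)), {
      n <- spec$n_poses
      k <- sample(idx, n, replace = TRUE)
      jit <- matrix(stats::rnorm(3 * n, sd = spec$mode_jitter), ncol = 3)
      e <- spec$e0 + stats::rnorm(n)
      poses <- lapply(seq_len(n), function(i)
        pose(native$ligand_id, sprintf("%s_p%04d", run_id, i),
             sweep(native$coords, 2, modes[k[i], ] + jit[i, ], "+"),
             energy = e[i], run_id = run_id))
      pose_pool(poses)
    })
  }
  list(run_a = gen("runA", idx_a), run_b = gen("runB", idx_b), toy = toy,
       modes = modes, modes_a = idx_a, modes_b = idx_b)
}

#' Prepare the toy site for CF computation
#'
#' Runs the ligand-free SASA, selects key atoms around the native ligand
#' placement and returns the CF schema.
#'
#' @param toy a [make_toy_site()] output.
#' @param n_points SASA sphere points.
#' @return list: `site` (with key atoms), `schema`.
#' @export
prepare_toy_site <- function(toy, n_points = 480) {
  site <- select_key_atoms(toy$site, list(atom_coords(toy$ligand$atoms)),
                           n_points = n_points)
  list(site = site, schema = cf_schema(site$key_atom_indices))
}

#' Full run-reproducibility experiment on synthetic paired runs
#'
#' Generates paired runs, computes their CF matrices, fits one GTM on the
#' combined pool, projects each run and evaluates [iri()].
#'
#' @param spec a [synthetic_spec()].
#' @param overlap shared-mode fraction.
#' @param p dominance threshold.
#' @param config GTM configuration for the shared map (modest default
#'   sized for pose ensembles of a few hundred).
#' @return the [iri()] result, with the fitted model and runs attached.
#' @export
run_iri_experiment <- function(spec, overlap, p = 0.85,
                               config = gtm_config(k_side = 7, m_side = 3,
                                                   rbf_width_factor = 1.0,
                                                   regularization = 0.1,
                                                   max_iter = 40)) {
  pr <- make_paired_runs(spec, overlap)
  prep <- prepare_toy_site(pr$toy)
  Xa <- cf_matrix(pr$run_a, pr$toy$ligand, prep$site, prep$schema)
  Xb <- cf_matrix(pr$run_b, pr$toy$ligand, prep$site, prep$schema)
  model <- fit_gtm(rbind(Xa, Xb), config)
  res <- iri(responsibilities(model, Xa), responsibilities(model, Xb), p = p)
  res$model <- model
  res$overlap <- overlap
  res
}

#' Generate a synthetic virtual-screening compound set
#'
#' Compounds fall in three classes: potent actives (`"top"`, pK in
#' 7.2-9.0), weak actives (`"weak"`, pK in 4.7-5.5) and decoys (`"decoy"`,
#' pK fixed at 3).  Each compound gets a pose ensemble in which the
#' fraction of poses contacting both site hot spots rises with pK at a
#' strength set by `effect_size` (0 decouples them); pose energies follow
#' the funnel plus a per-compound offset, and each compound carries a free-
#' ligand reference energy so a docking-score baseline can be computed.
#'
#' @param spec a [synthetic_spec()].
#' @param toy optional [make_toy_site()] output.
#' @return list: `compounds` (data.frame: compound_id, class, pk,
#'   free_energy), `pools` (named list of [pose_pool()]s), `toy`.
#' @export
make_screening_set <- function(spec = synthetic_spec(), toy = NULL) {
  if (is.null(toy)) toy <- make_toy_site(spec)
  native <- toy$native
  with_seed(derive_seed(spec$seed, "screening"), {
    classes <- c(rep("top", spec$n_top), rep("weak", spec$n_weak),
                 rep("decoy", spec$n_decoy))
    nC <- length(classes)
    pk <- ifelse(classes == "top", stats::runif(nC, 7.2, 9.0),
          ifelse(classes == "weak", stats::runif(nC, 4.7, 5.5), 3))
    ids <- sprintf("cmpd%03d", seq_len(nC))
    p_hot <- pmin(0.95, pmax(0.02, 0.15 + spec$effect_size * (pk - 3) / 6))
    offset <- stats::rnorm(nC, sd = 2)          # per-compound energy shift
    free_energy <- stats::rnorm(nC, sd = 1)
    pools <- vector("list", nC)
    np <- spec$n_poses_per_compound
    for (c in seq_len(nC)) {
      hot <- stats::runif(np) < p_hot[c]
      t <- ifelse(hot, abs(stats::rnorm(np, sd = 0.4)),
                  stats::runif(np, 3.5, 7.0))
      u <- random_unit(np)
      e <- spec$e0 + offset[c] + spec$funnel_slope * t +
        stats::rnorm(np, sd = spec$funnel_noise)
      poses <- lapply(seq_len(np), function(i)
        pose(ids[c], sprintf("%s_p%03d", ids[c], i),
             sweep(native$coords, 2, t[i] * u[i, ], "+"),
             energy = e[i], run_id = "screen", rmsd_to_native = t[i]))
      pools[[c]] <- pose_pool(poses)
    }
    names(pools) <- ids
    list(compounds = data.frame(compound_id = ids, class = classes, pk = pk,
                                free_energy = free_energy,
                                stringsAsFactors = FALSE),
         pools = pools, toy = toy)
  })
}

#' End-to-end synthetic virtual-screening experiment
#'
#' Generates the compound set, splits it into color and test halves
#' (stratified by class), fits a CF map on the color compounds' poses,
#' colors a pK landscape from Boltzmann-averaged AR vectors, predicts the
#' test compounds and compares the map-based ROC AUC with the
#' docking-score and hot-spot-contact baselines in both the TvO and AvD
#' scenarios.
#'
#' @param spec a [synthetic_spec()].
#' @param beta Boltzmann parameter for the AR vectors (0 = plain average).
#' @param config GTM configuration of the screening map.
#' @return list of AUCs (`auc_map`, `auc_de`, `auc_leu_o`, `auc_leu_nh`,
#'   `auc_leu_tot`, each a TvO/AvD pair), predictions and the fitted model.
#' @export
run_screening_experiment <- function(spec = synthetic_spec(), beta = 0,
                                     config = gtm_config(k_side = 10,
                                                         m_side = 4,
                                                         rbf_width_factor = 1.0,
                                                         regularization = 0.1,
                                                         max_iter = 30)) {
  set <- make_screening_set(spec)
  prep <- prepare_toy_site(set$toy)
  cmp <- set$compounds
  cfs <- lapply(set$pools, cf_matrix, lig = set$toy$ligand,
                site = prep$site, schema = prep$schema)
  is_color <- color_test_split(cmp$class, seed = spec$seed)
  frame <- do.call(rbind, cfs[is_color])
  model <- fit_gtm(frame, config)
  ar_of <- function(i) ar_vector(responsibilities(model, cfs[[i]]),
                                 pool_energies(set$pools[[i]]), beta = beta)
  AR <- t(vapply(seq_len(nrow(cmp)), function(i) as.numeric(ar_of(i)),
                 numeric(config$K)))
  # baselines on the test half
  de <- vapply(seq_len(nrow(cmp)), function(i)
    docking_score(set$pools[[i]], cmp$free_energy[i]), 0)
  o_id <- prep$site$hot_spots[1]; h_id <- prep$site$hot_spots[2]
  leu <- t(vapply(seq_len(nrow(cmp)), function(i) {
    X <- cfs[[i]]
    lo <- mean(X[, paste0("a", o_id, "_direct_n_contacts")])
    lnh <- mean(X[, paste0("a", h_id, "_direct_n_contacts")])
    ltot <- mean(X[, paste0("a", o_id, "_direct_n_contacts")] *
                 X[, paste0("a", h_id, "_direct_n_contacts")])
    c(lo, lnh, ltot)
  }, numeric(3)))
  test <- !is_color
  out <- list(model = model, beta = beta, is_color = is_color,
              compounds = cmp)
  for (sc in c("TvO", "AvD")) {
    s <- screen(AR[is_color, , drop = FALSE], cmp$pk[is_color],
                AR[test, , drop = FALSE], cmp$class[test], scenario = sc)
    pos <- s$positives; neg <- if (sc == "TvO") !pos else
      cmp$class[test] == "decoy"
    use <- pos | neg
    out[[paste0("auc_map_", tolower(sc))]] <- s$auc
    out[[paste0("pk_pred_", tolower(sc))]] <- s$pk_pred
    out[[paste0("auc_de_", tolower(sc))]] <-
      roc_auc(de[test][use], pos[use], higher_is_positive = FALSE)
    out[[paste0("auc_leu_o_", tolower(sc))]] <- roc_auc(leu[test, 1][use], pos[use])
    out[[paste0("auc_leu_nh_", tolower(sc))]] <- roc_auc(leu[test, 2][use], pos[use])
    out[[paste0("auc_leu_tot_", tolower(sc))]] <- roc_auc(leu[test, 3][use], pos[use])
  }
  out
}
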