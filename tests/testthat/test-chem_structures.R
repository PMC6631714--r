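# Domain types and file I/O.

test_that("Mol2 site round-trips with charges preserved at printed precision", {
  f <- write_toy_mol2(tempfile(fileext = ".mol2"), charges = c(-0.8, 0.4, 0.4))
  site <- read_site(f, "mol2")
  expect_identical(site$atoms$partial_charge, c(-0.8, 0.4, 0.4))
  expect_identical(site$atoms$element, c("O", "H", "H"))
  expect_equal(site$atoms$x, c(0, 0.96, -0.24))
  expect_length(site$key_atom_indices, 0)
  # reading twice yields identical content
  site2 <- read_site(f, "mol2")
  expect_identical(site$atoms, site2$atoms)
  # write -> read closes the loop bit-exact at 4-decimal charges
  f2 <- tempfile(fileext = ".mol2")
  write_site_mol2(site, f2)
  expect_identical(read_site(f2, "mol2")$atoms$partial_charge,
                   site$atoms$partial_charge)
})

test_that("H-bond roles follow the bonded-H donor / N,O acceptor rule", {
  f <- write_toy_mol2(tempfile(fileext = ".mol2"))
  site <- read_site(f, "mol2")
  expect_true(all(site$atoms$is_hbd[2:3]))   # H bonded to O
  expect_true(site$atoms$is_hba[1])          # O acceptor
  expect_false(site$atoms$is_hbd[1])
  # N carrying an H is not an acceptor; bare N is
  atoms <- atom_table(c("N", "H", "N"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0)))
  atoms <- assign_hbond_roles(atoms,
    data.frame(i = 1, j = 2, order = 1))
  expect_false(atoms$is_hba[1])
  expect_true(atoms$is_hba[3])
  expect_true(atoms$is_hbd[2])
})

test_that("degenerate and broken Mol2 inputs are handled explicitly", {
  f <- write_toy_mol2(tempfile(fileext = ".mol2"), charges = c(0, 0, 0))
  expect_warning(site <- read_site(f, "mol2"), "zero")
  expect_identical(site$atoms$partial_charge, c(0, 0, 0))
  bad <- tempfile(fileext = ".mol2")
  writeLines(c("not", "a", "mol2"), bad)
  expect_error(read_site(bad, "mol2"), "format error")
  expect_error(read_site(tempfile(), "mol2"), "not found")
})

test_that("PDB input triggers the fallback charge assigner with provenance", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1      -0.500   0.870   0.000  1.00  0.00           H",
    "END"), f)
  expect_warning(site <- read_site(f, "pdb"), "fallback")
  expect_identical(site$provenance$charge_source, "gasteiger-openbabel")
  expect_true(any(site$atoms$partial_charge != 0))
  # fallback assigner standalone gives the same charges
  expect_warning(site2 <- read_site(f, "pdb"), "fallback")
  expect_identical(site$atoms$partial_charge, site2$atoms$partial_charge)
})

test_that("SDF pose ensembles round-trip with energies and identifiers", {
  toy <- toy_fixture()
  spec <- synthetic_spec(seed = 7, n_poses = 5)
  ens <- make_pose_ensemble(spec, toy$native)
  f <- tempfile(fileext = ".sdf")
  write_poses_sdf(ens, toy$ligand, f)
  back <- read_poses(f, "sdf")
  expect_length(back, 5)
  expect_equal(vapply(back, function(p) p$energy, 0), pool_energies(ens),
               tolerance = 1e-10)
  expect_identical(vapply(back, function(p) p$conformer_id, ""),
                   vapply(ens$poses, function(p) p$conformer_id, ""))
  expect_identical(back[[1]]$ligand_id, "toy")
  expect_equal(back[[3]]$coords, ens$poses[[3]]$coords, tolerance = 1e-4)
})

test_that("pose reading rejects bad records and warns on empty files", {
  empty <- tempfile(fileext = ".sdf")
  file.create(empty)
  expect_warning(p <- read_poses(empty, "sdf"), "empty")
  expect_length(p, 0)
  # record missing the energy tag is named
  toy <- toy_fixture()
  ens <- make_pose_ensemble(synthetic_spec(seed = 7, n_poses = 2), toy$native)
  f <- tempfile(fileext = ".sdf")
  write_poses_sdf(ens, toy$ligand, f)
  expect_error(read_poses(f, "sdf", energy_tag = "no_such_tag"), "record 1")
})

test_that("Mol2 poses read through the sidecar energy CSV", {
  toy <- toy_fixture()
  ens <- make_pose_ensemble(synthetic_spec(seed = 8, n_poses = 3), toy$native)
  f <- tempfile(fileext = ".mol2")
  txt <- character(0)
  for (p in ens$poses) {
    s <- site_model(within(toy$ligand$atoms, {
      x <- p$coords[, 1]; y <- p$coords[, 2]; z <- p$coords[, 3]
    }))
    tmp <- tempfile(fileext = ".mol2")
    write_site_mol2(s, tmp)
    rec <- readLines(tmp)
    rec[2] <- p$conformer_id          # molecule name line
    txt <- c(txt, rec)
  }
  writeLines(txt, f)
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(conformer_id = vapply(ens$poses, function(p) p$conformer_id, ""),
                       energy = pool_energies(ens)), csv, row.names = FALSE)
  back <- read_poses(f, "mol2", energy_csv = csv, ligand_id = "toy")
  expect_length(back, 3)
  expect_equal(vapply(back, function(p) p$energy, 0), pool_energies(ens))
  expect_error(read_poses(f, "mol2"), "sidecar")
})

test_that("node tables round-trip bit-exact including undefined cells", {
  toy <- toy_fixture()
  X <- cf_matrix(make_pose_ensemble(synthetic_spec(seed = 9, n_poses = 30), toy$native),
                 toy$ligand, toy$site, toy$schema)
  m <- fit_gtm(X, gtm_config(k_side = 3, m_side = 2, max_iter = 10,
                             regularization = 0.1, rbf_width_factor = 1))
  R <- responsibilities(m, X)
  ls <- color_regression(m, R, seq_len(nrow(X)), eps = 0.5)
  f <- tempfile(fileext = ".csv")
  write_node_table(ls, f)
  tab <- read_node_table(f)
  expect_equal(nrow(tab), 9)
  v <- ls$node_values; v[!ls$defined] <- NA
  expect_identical(tab$value, v)                 # bit-exact for finite values
  expect_identical(tab$density, ls$node_density) # densities always written
  expect_error(write_node_table(list(), f))
})

test_that("atom table enforces invariants", {
  expect_error(atom_table("C", c(0, 0, Inf)), "finite")
  expect_warning(r <- vdw_radius(c("C", "Xx")), "unknown")
  expect_identical(r, c(1.70, 1.70))
  expect_true(all(atom_table(c("H", "O"), matrix(0, 2, 3))$vdw_radius > 0))
  expect_error(pose("l", "c", matrix(0, 2, 3), energy = NaN), "finite")
})
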