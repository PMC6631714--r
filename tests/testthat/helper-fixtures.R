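# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

toy_fixture <- function() fixture("toy", function() {
  spec <- synthetic_spec(seed = 42)
  toy <- make_toy_site(spec)
  prep <- prepare_toy_site(toy)
  list(site = prep$site, schema = prep$schema, ligand = toy$ligand,
       native = toy$native, hotspot_o = toy$hotspot_o,
       hotspot_h = toy$hotspot_h, spec = spec)
})

# A 3-atom water-like Mol2 with 4-decimal charges (the format's printed
# precision), used for round-trip checks.
write_toy_mol2 <- function(path, charges = c(-0.8, 0.4, 0.4)) {
  writeLines(c(
    "@<TRIPOS>MOLECULE", "toy", " 3 2 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("1 O1 0.000 0.000 0.000 O.2 1 RES1 %.4f", charges[1]),
    sprintf("2 H1 0.960 0.000 0.000 H 1 RES1 %.4f", charges[2]),
    sprintf("3 H2 -0.240 0.930 0.000 H 1 RES1 %.4f", charges[3]),
    "@<TRIPOS>BOND", "1 1 2 1", "2 1 3 1"), path)
  path
}

# Ethanol heavy-atom graph C-C-O (H-suppressed).
ethanol_ligand <- function(charged_o = FALSE) {
  atoms <- atom_table(c("C", "C", "O"),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0)),
                      formal_charge = c(0L, 0L, if (charged_o) -1L else 0L))
  ligand("ethanol", atoms, data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
}

# Minimal two-atom site with both atoms as key atoms; atom 1 at the origin.
two_atom_site <- function(separation = 100) {
  site_model(atom_table(c("C", "C"),
                        rbind(c(0, 0, 0), c(separation, 0, 0)),
                        partial_charge = c(0, 0)))
}

# Single-atom carbon "ligand" with configurable charge/roles.
point_ligand <- function(x, q = 0, hbd = FALSE, hba = FALSE) {
  a <- atom_table("C", matrix(x, ncol = 3), partial_charge = q)
  a$is_hbd <- hbd
  a$is_hba <- hba
  ligand("pt", a, data.frame(i = integer(0), j = integer(0), order = integer(0)))
}

# Exhaustive pairwise-comparison ROC AUC oracle (midrank ties), higher
# score = positive.
auc_oracle <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  w <- 0
  for (i in pos) for (j in neg)
    w <- w + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  w / (length(pos) * length(neg))
}

# Data sampled exactly on a 2D affine plane embedded in D dims.
plane_data <- function(n = 200, D = 10, seed = 42) {
  with_seed <- getFromNamespace("with_seed", "gtmdock")
  with_seed(seed, {
    B <- qr.Q(qr(matrix(rnorm(3 * D), D)))[, 1:2]
    Z <- matrix(runif(2 * n, -3, 3), n, 2)
    Z %*% t(B) + matrix(rep(rnorm(D), each = n), n)
  })
}
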