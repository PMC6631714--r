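# IRI, Q/R/M/F cross-prediction, native-pose ROC, AR vectors, screening.

one_hot_R <- function(counts) {
  # rows concentrated on nodes: counts[k] rows for node k
  K <- length(counts)
  do.call(rbind, lapply(seq_len(K), function(k) {
    if (!counts[k]) return(NULL)
    m <- matrix(0, counts[k], K); m[, k] <- 1; m
  }))
}

test_that("IRI is 0 for identical runs, 1 for disjoint runs, 1/3 for the 3-node case", {
  R <- one_hot_R(c(4, 3, 2))
  expect_equal(iri(R, R)$iri, 0)                       # every f_k = 0.5
  Ra <- one_hot_R(c(5, 0, 0)); Rb <- one_hot_R(c(0, 0, 5))
  expect_equal(iri(Ra, Rb)$iri, 1)
  # constructed D = {10,10,10}, f = {0.5, 0.9, 0.5}: only node 2 dominated
  Ra3 <- one_hot_R(c(5, 9, 5)); Rb3 <- one_hot_R(c(5, 1, 5))
  res <- iri(Ra3, Rb3, p = 0.85)
  expect_equal(res$iri, 10 / 30)
  expect_identical(which(res$irreproducible), 2L)
  expect_error(iri(Ra, Rb, p = 0.5), "ill-defined")
  expect_error(iri(Ra[0, , drop = FALSE], Rb), "non-empty")
})

test_that("IRI is monotone non-increasing in the dominance threshold", {
  ws <- getFromNamespace("with_seed", "gtmdock")
  Ra <- ws(3, matrix(runif(200), 20)); Ra <- Ra / rowSums(Ra)
  Rb <- ws(4, matrix(runif(300), 30)); Rb <- Rb / rowSums(Rb)
  vals <- vapply(c(0.55, 0.7, 0.85, 0.95), function(p) iri(Ra, Rb, p)$iri, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

identity_landscape <- function(values) {
  K <- length(values)
  structure(list(model = NULL, type = "regression", node_values = values,
                 node_density = rep(1, K), defined = rep(TRUE, K), eps = 0,
                 property = "rmsd"), class = "Landscape")
}

test_that("the Q/R/M/F labeler reproduces the constructed verdicts", {
  obs <- seq(0.2, 6, length.out = 20)
  eye <- diag(20)
  verdict <- function(pred) cross_predict_rmsd(identity_landscape(pred), eye, obs)
  vQ <- verdict(obs)                         # perfect
  expect_identical(vQ$label, "Q")
  expect_equal(vQ$r2, 1); expect_equal(vQ$ba, 1); expect_equal(vQ$auc, 1)
  vR <- verdict(2 * obs)                     # perfect order, wrong scale
  expect_identical(vR$label, "R")
  expect_equal(vR$auc, 1)
  expect_lt(vR$r2, 0)
  vF <- verdict(6.2 - obs)                   # anti-ordered
  expect_identical(vF$label, "F")
  expect_equal(vF$auc, 0)
  vM <- verdict(ifelse(seq_along(obs) %% 4 == 0, 6 - obs, obs))
  expect_identical(vM$label, "M")
  # independently recomputed criteria agree with the verdict fields
  predM <- ifelse(seq_along(obs) %% 4 == 0, 6 - obs, obs)
  expect_equal(vM$r2, 1 - sum((obs - predM)^2) / sum((obs - mean(obs))^2))
  expect_equal(vM$auc, auc_oracle(-predM, obs < 2))
})

test_that("every criteria triple receives exactly one label", {
  ws <- getFromNamespace("with_seed", "gtmdock")
  grid <- ws(7, cbind(runif(300, -1, 1.2), runif(300, 0, 1.2), runif(300, 0, 1.2)))
  labs <- apply(grid, 1, function(r)
    gtmdock:::qrmf_label(r[1], r[2], r[3]))
  expect_true(all(labs %in% c("Q", "R", "M", "F")))
  # rule order: Q beats R beats F
  expect_identical(gtmdock:::qrmf_label(0.8, 0.8, 0.9), "Q")
  expect_identical(gtmdock:::qrmf_label(0.2, 0.2, 0.9), "R")
  expect_identical(gtmdock:::qrmf_label(0.2, 0.2, 0.2), "F")
  expect_identical(gtmdock:::qrmf_label(0.7, 0.2, 0.2), "M")
})

test_that("single-class test sets fall back to an r2-only verdict, flagged", {
  obs <- seq(3, 6, length.out = 10)      # no native-like pose
  v <- cross_predict_rmsd(identity_landscape(obs), diag(10), obs)
  expect_true(v$degenerate)
  expect_true(is.na(v$auc))
  expect_identical(v$label, "Q")
})

test_that("native ranking AUC matches the exhaustive pairwise oracle", {
  expect_equal(native_ranking_roc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  expect_equal(native_ranking_roc(c(1, 2, 3), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(native_ranking_roc(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               0.5)
  expect_error(native_ranking_roc(1:3, c(TRUE, TRUE, TRUE)), "native-like")
  # exhaustive check on all small score/label combinations
  ws <- getFromNamespace("with_seed", "gtmdock")
  ws(13, for (rep in 1:30) {
    n <- sample(3:6, 1)
    score <- sample(1:4, n, replace = TRUE) + runif(n, 0, 0.01)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(native_ranking_roc(score, lab), auc_oracle(-score, lab),
                 tolerance = 1e-12)
    expect_equal(roc_auc(score, lab), auc_oracle(score, lab), tolerance = 1e-12)
  })
})

test_that("AR vectors honor the Boltzmann limits exactly", {
  ws <- getFromNamespace("with_seed", "gtmdock")
  R <- ws(17, matrix(runif(50), 5)); R <- R / rowSums(R)
  e <- c(-10, -8, -9.5, -7, -9.9)
  expect_equal(as.numeric(ar_vector(R, e, beta = 0)), colMeans(R),
               tolerance = 1e-12)
  expect_equal(as.numeric(ar_vector(R, e, beta = 1e6)), as.numeric(R[1, ]),
               tolerance = 1e-9)
  expect_equal(as.numeric(ar_vector(R, e, beta = Inf)), as.numeric(R[1, ]))
  expect_equal(sum(ar_vector(R, e, beta = 0.3)), 1, tolerance = 1e-9)
  # equal energies: plain mean at every beta
  e2 <- rep(-5, 5)
  for (b in c(0, 0.3, 3, 100))
    expect_equal(as.numeric(ar_vector(R, e2, beta = b)), colMeans(R),
                 tolerance = 1e-12)
  # continuity in beta near the discussed peak
  a1 <- as.numeric(ar_vector(R, e, 0.3))
  a2 <- as.numeric(ar_vector(R, e, 0.3 + 1e-7))
  expect_lt(max(abs(a1 - a2)), 1e-6)
  expect_error(ar_vector(R, e[1:3], 0), "one energy per pose")
  expect_error(ar_vector(R, rep(NA_real_, 5), 0), "finite")
})

test_that("pK landscapes predict weighted means of the color compounds", {
  K <- 8
  # single color compound: identical test AR recovers its pK
  ar1 <- rep(1 / K, K)
  s1 <- screen(matrix(ar1, 1), 6.5, matrix(ar1, 1), "top", "TvO")
  expect_equal(s1$pk_pred, 6.5)
  expect_true(is.na(s1$auc))               # one-class test set
  # two color compounds on disjoint nodes, pK 5 and 9, test split 50/50
  arA <- c(1, 0, 0, 0, 0, 0, 0, 0)
  arB <- c(0, 1, 0, 0, 0, 0, 0, 0)
  s2 <- screen(rbind(arA, arB), c(5, 9),
               rbind((arA + arB) / 2, arA), c("top", "decoy"), "TvO")
  expect_equal(s2$pk_pred, c(7, 5))
  expect_equal(s2$auc, 1)
  # zero-coverage test compound is excluded and counted
  arC <- c(0, 0, 0, 0, 0, 0, 0, 1)
  s3 <- screen(rbind(arA, arB), c(5, 9), rbind(arA, arC),
               c("top", "decoy"), "TvO")
  expect_identical(s3$n_excluded, 1L)
  expect_true(is.na(s3$pk_pred[2]))
  expect_error(screen(matrix(numeric(0), 0, K), numeric(0), matrix(ar1, 1),
                      "top"), "non-empty")
})

test_that("screening at beta 0 equals screening with plain-average AR", {
  toy <- toy_fixture()
  spec <- synthetic_spec(seed = 19, n_top = 6, n_weak = 5, n_decoy = 6,
                         n_poses_per_compound = 4)
  set <- make_screening_set(spec, toy = list(site = toy$site,
                                             ligand = toy$ligand,
                                             native = toy$native,
                                             hotspot_o = 1L, hotspot_h = 2L))
  cfs <- lapply(set$pools, cf_matrix, lig = toy$ligand, site = toy$site,
                schema = toy$schema)
  m <- fit_gtm(do.call(rbind, cfs), gtm_config(4, 2, 1, 0.1, max_iter = 15))
  ar_beta0 <- t(sapply(seq_along(cfs), function(i)
    ar_vector(responsibilities(m, cfs[[i]]), pool_energies(set$pools[[i]]), 0)))
  ar_plain <- t(sapply(seq_along(cfs), function(i)
    colMeans(responsibilities(m, cfs[[i]]))))
  expect_equal(ar_beta0, ar_plain, tolerance = 1e-12)
  cls <- set$compounds$class
  s_a <- screen(ar_beta0[1:9, ], set$compounds$pk[1:9], ar_beta0[10:17, ],
                cls[10:17], "AvD")
  s_b <- screen(ar_plain[1:9, ], set$compounds$pk[1:9], ar_plain[10:17, ],
                cls[10:17], "AvD")
  expect_equal(s_a$pk_pred, s_b$pk_pred, tolerance = 1e-12)
})
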