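# Docking-specific analyses on fitted maps: run-reproducibility index (IRI),
# explorer-based RMSD cross-prediction with Q/R/M/F verdicts, native-pose
# ranking ROC, Boltzmann-weighted averaged-responsibility (AR) vectors and
# virtual-screening landscapes.

#' ROC AUC with midrank tie handling
#'
#' @param score numeric ranking criterion.
#' @param positive logical (or 0/1) class labels.
#' @param higher_is_positive does a larger score indicate the positive
#'   class?  Use `FALSE` for ascending-RMSD or ascending-energy rankings.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, positive, higher_is_positive = TRUE) {
  positive <- as.logical(positive)
  if (!any(positive) || all(positive))
    stopf("ROC AUC needs both classes present")
  r <- pROC::roc(response = positive, predictor = as.numeric(score),
                 direction = if (higher_is_positive) "<" else ">",
                 quiet = TRUE, levels = c(FALSE, TRUE))
  as.numeric(pROC::auc(r))
}

#' Irreproducibility Index IRI(p)
#'
#' Fraction of the total map density accumulated in nodes whose population
#' stems predominantly (> p) from one of two docking runs projected on the
#' same map.  0 for perfectly mixed runs, 1 for runs occupying disjoint
#' nodes.
#'
#' @param R_runA,R_runB responsibility matrices of the two runs on one map.
#' @param p dominance threshold in (0.5, 1], default 0.85.
#' @return object of class `IRIResult`: `iri`, per-node dominance fractions
#'   and densities.
#' @export
iri <- function(R_runA, R_runB, p = 0.85) {
  if (p <= 0.5 || p > 1) stopf("p must lie in (0.5, 1]: dominance is ill-defined otherwise")
  if (!nrow(R_runA) || !nrow(R_runB)) stopf("both runs must be non-empty")
  if (ncol(R_runA) != ncol(R_runB)) stopf("runs projected on different maps")
  CA <- colSums(R_runA)
  CB <- colSums(R_runB)
  D <- CA + CB
  f <- ifelse(D > 0, CA / D, NA_real_)          # 0/0 nodes excluded
  dom <- pmax(f, 1 - f)
  irrep <- !is.na(dom) & dom > p
  structure(list(iri = sum(D[irrep]) / sum(D), p = p,
                 dominance = dom, density = D, irreproducible = irrep),
            class = "IRIResult")
}

#' @export
print.IRIResult <- function(x, ...) {
  cat(sprintf("IRI(%.0f%%) = %.4f (%d of %d populated nodes one-run dominated)\n",
              100 * x$p, x$iri, sum(x$irreproducible), sum(x$density > 0)))
  invisible(x)
}

qrmf_label <- function(r2, ba, auc) {
  crit <- c(r2, ba, auc)
  crit[is.na(crit)] <- -Inf
  if (all(crit > 0.75)) return("Q")
  if (is.finite(crit[3]) && crit[3] > 0.8) return("R")
  if (all(crit <= 0.6)) return("F")
  "M"
}

#' Explorer-based RMSD cross-prediction verdict
#'
#' Predicts RMSD of test poses from an explorer ligand's RMSD landscape and
#' scores the prediction three ways: determination coefficient
#' `r2 = 1 - SSE/SST`, balanced accuracy of the native-like call
#' (predicted < 2 A vs observed < 2 A) and ROC AUC of prioritizing observed
#' native-like poses by ascending predicted RMSD.  Verdicts: `Q` if all
#' three exceed 0.75; else `R` if AUC exceeds 0.8; `F` if none exceeds 0.6;
#' `M` otherwise.  Test sets lacking one of the two classes get a verdict
#' from r2 alone, flagged.
#'
#' @param explorer_landscape RMSD [color_regression()] landscape (observed
#'   values capped consistently with its coloring).
#' @param R_new responsibilities of the test poses on the same map.
#' @param observed_rmsd observed RMSD of the test poses (capped).
#' @param threshold native-like threshold, Angstrom (strict <, default 2).
#' @param coverage_min forwarded to [predict.Landscape()]; undefined
#'   predictions are imputed with the landscape's density-weighted mean.
#' @return object of class `CrossPredVerdict` (`r2`, `ba`, `auc`, `label`,
#'   `degenerate` flag).
#' @export
cross_predict_rmsd <- function(explorer_landscape, R_new, observed_rmsd,
                               threshold = 2.0, coverage_min = 0.1) {
  pr <- predict(explorer_landscape, R_new, coverage_min = coverage_min)
  yhat <- pr$pred
  if (anyNA(yhat)) {
    def <- explorer_landscape$defined
    mu <- sum(explorer_landscape$node_values[def] *
              explorer_landscape$node_density[def]) /
          sum(explorer_landscape$node_density[def])
    yhat[is.na(yhat)] <- mu
  }
  obs <- observed_rmsd
  r2 <- 1 - sum((obs - yhat)^2) / sum((obs - mean(obs))^2)
  obs_nat <- is_native_like(obs, threshold)
  pred_nat <- is_native_like(yhat, threshold)
  degenerate <- !any(obs_nat) || all(obs_nat)
  if (degenerate) {
    ba <- auc <- NA_real_
  } else {
    sens <- sum(pred_nat & obs_nat) / sum(obs_nat)
    spec <- sum(!pred_nat & !obs_nat) / sum(!obs_nat)
    ba <- (sens + spec) / 2
    auc <- roc_auc(yhat, obs_nat, higher_is_positive = FALSE)
  }
  label <- if (degenerate) {
    if (r2 > 0.75) "Q" else if (r2 <= 0.6) "F" else "M"
  } else qrmf_label(r2, ba, auc)
  structure(list(r2 = r2, ba = ba, auc = auc,
                 label = label, degenerate = degenerate,
                 n_undefined = pr$n_undefined),
            class = "CrossPredVerdict")
}

#' @export
print.CrossPredVerdict <- function(x, ...) {
  cat(sprintf("CrossPredVerdict: %s (r2 = %.3f, BA = %.3f, AUC = %.3f)%s\n",
              x$label, x$r2, x$ba, x$auc,
              if (x$degenerate) " [single-class test set: r2 only]" else ""))
  invisible(x)
}

#' Native-pose ranking ROC AUC
#'
#' Ranks poses by a score where lower is better (predicted RMSD or energy,
#' ascending) and measures how well native-like poses are prioritized.
#'
#' @param score per-pose ranking criterion (lower = better).
#' @param native_like logical labels.
#' @return ROC AUC (ties handled by midrank).
#' @export
native_ranking_roc <- function(score, native_like) {
  if (!any(native_like) || all(native_like))
    stopf("need at least one native-like and one other pose")
  if (length(unique(score)) == 1) return(0.5)   # all tied: chance by midrank
  roc_auc(score, native_like, higher_is_positive = FALSE)
}

#' Boltzmann-weighted averaged-responsibility (AR) vector
#'
#' `AR_k = sum_n exp(-beta E_n) R_nk / sum_n exp(-beta E_n)` over a
#' compound's docked poses (energies shifted by their minimum before
#' exponentiation, which leaves the weights unchanged but avoids overflow).
#' `beta = 0` is plain averaging; `beta -> Inf` converges to the single
#' most stable pose's responsibility row.  Sums to 1.
#'
#' @param R responsibilities of the compound's poses (N x K).
#' @param energies pose energies, kcal/mol (finite).
#' @param beta Boltzmann parameter, 1/(kcal/mol), >= 0 (`Inf` allowed).
#' @param compound_id optional identifier attribute.
#' @return K-vector of class `ARVector` summing to 1.
#' @export
ar_vector <- function(R, energies, beta = 0, compound_id = NULL) {
  if (!nrow(R)) stopf("at least one pose required")
  if (length(energies) != nrow(R)) stopf("one energy per pose required")
  if (any(!is.finite(energies))) stopf("energies must be finite")
  if (beta < 0) stopf("beta must be >= 0")
  if (is.infinite(beta)) {
    w <- as.numeric(energies == min(energies))
  } else {
    w <- exp(-beta * (energies - min(energies)))
  }
  ar <- as.numeric(crossprod(R, w)) / sum(w)
  structure(ar, class = "ARVector", beta = beta, compound_id = compound_id)
}

#' Color a pK landscape from AR vectors and predict test compounds
#'
#' Node values are AR-weighted means of the color compounds' pK:
#' `v_k = sum_C AR_k^C pK_C / sum_C AR_k^C` where the summed AR density
#' exceeds `eps`.  Each test compound's prediction is its AR-weighted mean
#' over defined nodes, renormalized; compounds with zero coverage are
#' excluded from the ROC and counted.  Scenarios: `"TvO"` ranks potent
#' actives (class `"top"`) against everything else; `"AvD"` ranks actives
#' (`"top"` and `"weak"`) against decoys only.
#'
#' @param color_ar matrix of AR vectors (rows = color compounds).
#' @param color_pk pK values of the color compounds (decoys conventionally
#'   pK = 3).
#' @param test_ar matrix of AR vectors of the test compounds.
#' @param test_class class labels of the test compounds
#'   (`"top"`, `"weak"`, `"decoy"`).
#' @param scenario `"TvO"` or `"AvD"`.
#' @param eps node defined-ness threshold on summed AR density.
#' @param coverage_min minimum coverage for a defined prediction.
#' @return list: `pk_pred`, `auc`, `coverage`, `n_excluded`, `positives`.
#' @export
screen <- function(color_ar, color_pk, test_ar, test_class,
                   scenario = c("TvO", "AvD"), eps = NULL,
                   coverage_min = 1e-6) {
  scenario <- match.arg(scenario)
  if (!nrow(color_ar)) stopf("color set must be non-empty")
  if (length(color_pk) != nrow(color_ar)) stopf("one pK per color compound")
  if (is.null(eps)) eps <- 1e-6 * nrow(color_ar) / ncol(color_ar)
  density <- colSums(color_ar)
  defined <- density > eps
  if (!any(defined)) stopf("no populated nodes in pK landscape")
  v <- as.numeric(crossprod(color_ar[, defined, drop = FALSE], color_pk)) /
    density[defined]
  Rd <- test_ar[, defined, drop = FALSE]
  coverage <- unname(rowSums(Rd))
  pk_pred <- as.numeric(Rd %*% v) / coverage
  pk_pred[coverage < coverage_min] <- NA_real_
  keep <- !is.na(pk_pred)
  positives <- switch(scenario,
    TvO = test_class == "top",
    AvD = test_class %in% c("top", "weak"))
  negatives <- switch(scenario,
    TvO = !positives,
    AvD = test_class == "decoy")
  use <- keep & (positives | negatives)
  auc <- if (any(positives[use]) && any(negatives[use]))
    roc_auc(pk_pred[use], positives[use]) else NA_real_
  list(pk_pred = pk_pred, auc = auc, coverage = coverage,
       n_excluded = sum(!keep), positives = positives, scenario = scenario)
}

#' Seeded stratified half-split into color and test sets
#'
#' @param classes class labels.
#' @param seed integer seed.
#' @return logical vector, `TRUE` for the color half.
#' @export
color_test_split <- function(classes, seed = 1) {
  with_seed(derive_seed(seed, "split"), {
    color <- rep(FALSE, length(classes))
    for (cl in unique(classes)) {
      idx <- sample(which(classes == cl))
      color[idx[seq_len(ceiling(length(idx) / 2))]] <- TRUE
    }
    color
  })
}
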