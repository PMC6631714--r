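# Property and class landscapes on a fitted map: coloring, prediction with
# an applicability-domain coverage weight, cross-validated Q2, map fitness
# and evolutionary hyperparameter selection.

default_eps <- function(R) 1e-6 * nrow(R) / ncol(R)

#' Color a regression landscape
#'
#' Node values are the responsibility-weighted means of the property over
#' resident items: `v_k = sum_n R_nk y_n / sum_n R_nk`, defined where the
#' node density exceeds `eps`.
#'
#' @param model a [fit_gtm()] model.
#' @param R N x K responsibilities of the coloring items.
#' @param y property values, length N.
#' @param eps minimum node density for a node to be defined
#'   (default `1e-6 * N / K`).
#' @param property property name (metadata).
#' @return object of class `Landscape`.
#' @export
color_regression <- function(model, R, y, eps = NULL, property = "y") {
  if (length(y) != nrow(R)) stopf("length(y) != nrow(R)")
  if (is.null(eps)) eps <- default_eps(R)
  density <- colSums(R)
  defined <- density > eps
  if (!any(defined)) stopf("no populated nodes: landscape undefined everywhere")
  v <- rep(NA_real_, ncol(R))
  v[defined] <- as.numeric(crossprod(R[, defined, drop = FALSE], y)) / density[defined]
  structure(list(model = model, type = "regression", node_values = v,
                 node_density = density, defined = defined, eps = eps,
                 property = property),
            class = "Landscape")
}

#' Color a classification landscape
#'
#' Stores the per-class cumulated responsibilities `CR_k^C`; the class with
#' maximal `CR` wins each node (ties broken to the lower class index and
#' flagged).  The fuzzy node value is the responsibility-weighted mean of
#' the numeric class labels, so it always lies within the label range.
#'
#' @param model a [fit_gtm()] model.
#' @param R N x K responsibilities.
#' @param labels class labels (factor, character or numeric); numeric labels
#'   are used as-is for the fuzzy values, otherwise level indices are used.
#' @param eps node defined-ness threshold as in [color_regression()].
#' @return object of class `Landscape` (type `"class"`).
#' @export
color_class <- function(model, R, labels, eps = NULL) {
  if (length(labels) != nrow(R)) stopf("length(labels) != nrow(R)")
  f <- factor(labels)
  if (nlevels(f) < 2) warnf("single-class input: degenerate class landscape")
  num <- suppressWarnings(as.numeric(levels(f)))
  label_values <- if (anyNA(num)) seq_len(nlevels(f)) else num
  if (is.null(eps)) eps <- default_eps(R)
  CR <- sapply(levels(f), function(cl)
    cumulated_responsibility(R, which(f == cl)))
  if (nlevels(f) == 1) CR <- matrix(CR, ncol = 1, dimnames = list(NULL, levels(f)))
  density <- rowSums(CR)
  defined <- density > eps
  winner <- apply(CR, 1, which.max)              # ties -> lower class index
  tie <- apply(CR, 1, function(r) sum(r == max(r)) > 1)
  v <- rep(NA_real_, nrow(CR))
  v[defined] <- (CR[defined, , drop = FALSE] %*% label_values) / density[defined]
  structure(list(model = model, type = "class", node_values = v,
                 node_density = density, defined = defined, eps = eps,
                 class_density = CR, classes = levels(f),
                 label_values = label_values, winner = winner, tie = tie,
                 property = "class"),
            class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape (%s, '%s'): %d/%d nodes defined, total density %.1f\n",
              x$type, x$property, sum(x$defined), length(x$defined),
              sum(x$node_density)))
  invisible(x)
}

#' Predict properties of projected items from a landscape
#'
#' `yhat_n = sum_{k defined} R_nk v_k / sum_{k defined} R_nk`; the coverage
#' `sum_{k defined} R_nk` is the applicability-domain weight.  Items whose
#' coverage falls below `coverage_min` ("white spots") get `NA` and are
#' counted.
#'
#' @param object a colored `Landscape`.
#' @param R_new responsibilities of the items to predict.
#' @param coverage_min minimum coverage for a defined prediction.
#' @param ... unused.
#' @return list with `pred`, `coverage`, `n_undefined`.
#' @export
predict.Landscape <- function(object, R_new, coverage_min = 0.1, ...) {
  def <- object$defined
  v <- object$node_values[def]
  Rd <- R_new[, def, drop = FALSE]
  coverage <- rowSums(Rd)
  pred <- as.numeric(Rd %*% v) / coverage
  pred[coverage < coverage_min] <- NA_real_
  list(pred = pred, coverage = coverage,
       n_undefined = sum(coverage < coverage_min))
}

# Stratified fold assignment: quartile bins of y, shuffled round-robin.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    qs <- stats::quantile(y, probs = seq(0, 1, length.out = 5), type = 7)
    bin <- cut(y, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
    if (anyNA(bin)) bin[is.na(bin)] <- 1
    fold <- integer(length(y))
    for (b in unique(bin)) {
      idx <- sample(which(bin == b))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validated landscape Q2
#'
#' Repeated k-fold CV of a property landscape: each fold's items are
#' predicted from a landscape colored on the remaining items (fixed
#' manifold by default; set `refit = TRUE` to refit the manifold per fold).
#' `Q2 = 1 - SSE/SST` with SST about the training mean; predictions with
#' insufficient coverage are imputed with the training mean and counted.
#' Folds stratify by property quartile.
#'
#' @param model a fitted [fit_gtm()] model (or a [gtm_config()] when
#'   `refit = TRUE`).
#' @param data N x D descriptor matrix.
#' @param y property values.
#' @param folds,repeats CV layout (default 3 x 3).
#' @param seed integer seed for the fold draws.
#' @param refit refit the manifold on each training split (default: fixed
#'   manifold, landscape re-colored only).
#' @param coverage_min forwarded to [predict.Landscape()].
#' @return object of class `CVReport`: per-fold and per-repeat Q2, mean,
#'   SD, RMSE, imputed-prediction count.
#' @export
cross_validate <- function(model, data, y, folds = 3, repeats = 3, seed = 1,
                           refit = FALSE, coverage_min = 0.1) {
  N <- nrow(data)
  if (N < folds) stopf("need at least as many items as folds")
  if (!refit) R_all <- responsibilities(model, data)
  q2_fold <- matrix(NA_real_, repeats, folds)
  rmse_fold <- matrix(NA_real_, repeats, folds)
  q2_repeat <- numeric(repeats)
  n_imputed <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, derive_seed(seed, paste0("cv", r)))
    res_all <- obs_all <- numeric(0)
    for (f in seq_len(folds)) {
      test <- fold == f
      if (refit) {
        cfg <- if (inherits(model, "GTMModel")) model$config else model
        m <- fit_gtm(data[!test, , drop = FALSE], cfg)
        R_tr <- responsibilities(m, data[!test, , drop = FALSE])
        R_te <- responsibilities(m, data[test, , drop = FALSE])
        ls <- color_regression(m, R_tr, y[!test])
      } else {
        R_tr <- R_all[!test, , drop = FALSE]
        R_te <- R_all[test, , drop = FALSE]
        ls <- color_regression(model, R_tr, y[!test])
      }
      pr <- predict(ls, R_te, coverage_min = coverage_min)
      mu_tr <- mean(y[!test])
      yhat <- pr$pred
      n_imputed <- n_imputed + sum(is.na(yhat))
      yhat[is.na(yhat)] <- mu_tr
      sse <- sum((y[test] - yhat)^2)
      sst <- sum((y[test] - mu_tr)^2)
      q2_fold[r, f] <- 1 - sse / sst
      rmse_fold[r, f] <- sqrt(mean((y[test] - yhat)^2))
      res_all <- c(res_all, y[test] - yhat)
      obs_all <- c(obs_all, y[test] - mu_tr)
    }
    q2_repeat[r] <- 1 - sum(res_all^2) / sum(obs_all^2)
  }
  structure(list(q2_fold = q2_fold, q2_repeat = q2_repeat,
                 q2_mean = mean(q2_fold), q2_sd = stats::sd(as.numeric(q2_fold)),
                 rmse = mean(rmse_fold), folds = folds, repeats = repeats,
                 seed = seed, n_imputed = n_imputed),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: %dx%d-fold, mean Q2 = %.3f (SD %.3f), RMSE = %.3f, %d imputed\n",
              x$repeats, x$folds, x$q2_mean, x$q2_sd, x$rmse, x$n_imputed))
  invisible(x)
}

#' Map fitness from cross-validation reports
#'
#' Pools the per-repeat Q2 values of one report per property; fitness is
#' their mean minus one standard deviation.
#'
#' @param reports list of [cross_validate()] reports (one per property).
#' @return object of class `MapFitness` (`fitness`, `q2_values`, per-report
#'   means).
#' @export
map_fitness <- function(reports) {
  if (inherits(reports, "CVReport")) reports <- list(reports)
  q2 <- unlist(lapply(reports, function(r) r$q2_repeat))
  structure(list(fitness = mean(q2) - stats::sd(q2), q2_values = q2,
                 per_property = vapply(reports, function(r) r$q2_mean, 0)),
            class = "MapFitness")
}

genome_config <- function(genome, space) {
  vals <- lapply(seq_along(space), function(i) space[[i]][[genome[i]]])
  names(vals) <- names(space)
  vals
}

#' Evolutionary selection of map hyperparameters
#'
#' Elitist genetic search over a discrete space of GTM hyperparameters and
#' descriptor/frame-set choices.  Each candidate data set in `data_sets`
#' stands for one frame-set (and, for hybrid searches, one fragment-scheme)
#' choice; the `data_set` gene selects among them.  Fitness of a candidate
#' is [map_fitness()] over the supplied properties (mean per-repeat Q2
#' minus one SD).  Deterministic under `seed`; `budget` counts fitness
#' evaluations (cached genomes are free).
#'
#' @param search_space named list of candidate vectors; recognized names:
#'   `k_side`, `m_side`, `rbf_width_factor`, `regularization`, `data_set`.
#'   A missing `data_set` entry is added when several data sets are given.
#' @param data_sets a descriptor matrix or list of matrices.
#' @param properties named list of property vectors per data set: either a
#'   single list of vectors (shared row layout) or a list parallel to
#'   `data_sets`, each a named list of vectors.
#' @param budget maximum fitness evaluations (default 200).
#' @param seed integer seed.
#' @param population,tournament,mutation_rate,crossover_rate GA controls.
#' @param folds,repeats CV layout per evaluation.
#' @param base_config [gtm_config()] supplying non-searched parameters.
#' @return list: `best_config` (a `GTMConfig`), `best_data_set`,
#'   `best_fitness`, `trace` (one row per evaluation), `best_model`.
#' @export
optimize_map <- function(search_space, data_sets, properties, budget = 200,
                         seed = 1, population = 20, tournament = 3,
                         mutation_rate = 0.2, crossover_rate = 0.5,
                         folds = 3, repeats = 3, base_config = gtm_config()) {
  if (!length(search_space)) stopf("empty search space")
  if (is.matrix(data_sets) || is.data.frame(data_sets))
    data_sets <- list(as.matrix(data_sets))
  multi <- length(data_sets) > 1
  if (multi && is.null(search_space$data_set))
    search_space$data_set <- seq_along(data_sets)
  # properties normalized to one named list per data set
  if (!is.null(names(properties)) && is.numeric(properties[[1]]))
    properties <- rep(list(properties), length(data_sets))
  sizes <- vapply(search_space, length, 0L)
  if (any(sizes == 0)) stopf("empty candidate list in search space")

  evaluate <- function(genome) {
    cfgv <- genome_config(genome, search_space)
    ds <- if (!is.null(cfgv$data_set)) cfgv$data_set else 1L
    cfg <- base_config
    for (nm in intersect(names(cfgv),
                         c("k_side", "m_side", "rbf_width_factor", "regularization")))
      cfg[[nm]] <- cfgv[[nm]]
    cfg <- do.call(gtm_config, cfg[c("k_side", "m_side", "rbf_width_factor",
                                     "regularization", "max_iter",
                                     "ll_tolerance", "scale", "seed")])
    X <- data_sets[[ds]]
    model <- fit_gtm(X, cfg)
    reports <- lapply(properties[[ds]], function(y)
      cross_validate(model, X, y, folds = folds, repeats = repeats,
                     seed = derive_seed(seed, "cvfold")))
    list(fitness = map_fitness(reports)$fitness, config = cfg, data_set = ds,
         model = model)
  }

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  trace <- list()
  eval_cached <- function(genome) {
    key <- paste(genome, collapse = "-")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n_eval >= budget) return(NULL)
    out <- evaluate(genome)
    n_eval <<- n_eval + 1L
    trace[[length(trace) + 1L]] <<- data.frame(eval = n_eval, genome = key,
                                               fitness = out$fitness)
    cache[[key]] <- out
    out
  }

  total <- prod(sizes)
  with_seed(derive_seed(seed, "ga"), {
    pop_n <- min(population, max(2, total))
    genomes <- unique(lapply(seq_len(pop_n * 4), function(i)
      vapply(sizes, function(s) sample.int(s, 1), 0L)))
    genomes <- genomes[seq_len(min(length(genomes), pop_n, total))]
    scored <- list()
    for (g in genomes) {
      r <- eval_cached(g)
      if (is.null(r)) break
      scored[[length(scored) + 1]] <- list(genome = g, fitness = r$fitness)
    }
    attempts <- 0L
    while (n_eval < budget && total > 1 &&
           length(ls(cache)) < total && attempts < 50 * budget) {
      attempts <- attempts + 1L
      fit <- vapply(scored, function(s) s$fitness, 0)
      pick <- function() {
        cand <- sample.int(length(scored), min(tournament, length(scored)))
        scored[[cand[which.max(fit[cand])]]]$genome
      }
      a <- pick(); b <- pick()
      child <- ifelse(stats::runif(length(a)) < crossover_rate, a, b)
      mut <- stats::runif(length(child)) < mutation_rate
      child[mut] <- vapply(which(mut), function(i) sample.int(sizes[i], 1), 0L)
      child <- as.integer(child)
      r <- eval_cached(child)
      if (is.null(r)) break
      scored[[length(scored) + 1]] <- list(genome = child, fitness = r$fitness)
      # elitist truncation back to the population size
      keep <- order(vapply(scored, function(s) s$fitness, 0),
                    decreasing = TRUE)[seq_len(min(pop_n, length(scored)))]
      scored <- scored[keep]
    }
  })
  trace <- do.call(rbind, trace)
  best_key <- trace$genome[which.max(trace$fitness)]
  best <- cache[[best_key]]
  list(best_config = best$config, best_data_set = best$data_set,
       best_fitness = best$fitness, trace = trace, best_model = best$model)
}
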