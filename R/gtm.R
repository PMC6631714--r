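# Generative Topographic Mapping core.
#
# A K-node 2D latent grid maps through an RBF manifold y(x; W) into
# descriptor space as a constrained mixture of K isotropic Gaussians with a
# shared noise precision (GTM's own precision, distinct from the Boltzmann
# beta of AR vectors).  Fitting is EM; responsibilities R_nk are the
# posterior node memberships used for every landscape.

#' GTM hyperparameter record
#'
#' Defaults echo the reference contact-fingerprint map parameterisation
#' (29 x 29 nodes, 144 RBFs, width factor 1.8, regularization 6.61); the
#' conventions those numbers plug into (what the width factor multiplies,
#' how the regularization is scaled) are this package's own, so they are
#' defaults by name rather than reproducible outcomes.
#'
#' @param k_side latent grid side; K = k_side^2 nodes.
#' @param m_side RBF grid side; M = m_side^2 basis functions.
#' @param rbf_width_factor RBF width as a multiple of the RBF-center spacing.
#' @param regularization weight-decay coefficient lambda (>= 0) on the
#'   non-bias rows of W.
#' @param max_iter,ll_tolerance EM stopping rule (relative log-likelihood
#'   change).
#' @param scale logical: unit-variance column scaling of the training data
#'   (descriptor blocks of mixed units); centering always happens.
#' @param seed integer seed recorded with the model.
#' @return object of class `GTMConfig`.
#' @export
gtm_config <- function(k_side = 29, m_side = 12, rbf_width_factor = 1.8,
                       regularization = 6.61, max_iter = 100,
                       ll_tolerance = 1e-5, scale = FALSE, seed = 1) {
  if (k_side < 2 || m_side < 1) stopf("k_side >= 2 and m_side >= 1 required")
  if (rbf_width_factor <= 0) stopf("rbf_width_factor must be > 0")
  if (regularization < 0) stopf("regularization must be >= 0")
  structure(list(k_side = as.integer(k_side), m_side = as.integer(m_side),
                 K = as.integer(k_side^2), M = as.integer(m_side^2),
                 rbf_width_factor = rbf_width_factor,
                 regularization = regularization, max_iter = max_iter,
                 ll_tolerance = ll_tolerance, scale = scale,
                 seed = as.integer(seed)),
            class = "GTMConfig")
}

latent_grid <- function(side) {
  g <- if (side == 1) 0 else seq(-1, 1, length.out = side)
  as.matrix(expand.grid(x = g, y = g))
}

# Basis matrix: M Gaussian RBFs + two linear columns + bias.  The linear
# columns make affine planes exactly representable by the manifold.
gtm_basis <- function(nodes, centers, sigma) {
  d2 <- cross_dist2(nodes, centers)
  cbind(exp(-d2 / (2 * sigma^2)), nodes, 1)
}

#' Fit a GTM to a descriptor matrix
#'
#' EM maximizes the data log-likelihood of the K-component isotropic
#' Gaussian mixture with means `y_k = Phi_k W`.  The M-step solves
#' `(Phi' G Phi + (lambda/beta) I) W = Phi' R T` (weight decay excluded for
#' the bias row), followed by the closed-form noise-precision update.
#' Initialization is deterministic: W from the first two principal
#' components (largest-magnitude loading forced positive), noise precision
#' from the third-PC variance or half the inter-node image spacing,
#' whichever is larger as variance.
#'
#' @param data N x D numeric matrix, N >= 3, D >= 2, no NaNs.
#' @param config a [gtm_config()].
#' @return object of class `GTMModel` (weights, noise precision, basis,
#'   centering record, per-iteration traces).  `ll_trace` records the data
#'   log-likelihood and `objective_trace` the penalized EM objective
#'   (identical when `regularization = 0`); the latter is the quantity EM
#'   increases monotonically and the one the stopping rule watches.
#' @export
fit_gtm <- function(data, config = gtm_config()) {
  T0 <- as.matrix(data)
  N <- nrow(T0); D <- ncol(T0)
  if (N < 3 || D < 2) stopf("need N >= 3 and D >= 2 (got %d x %d)", N, D)
  if (any(!is.finite(T0))) stopf("data contains non-finite values")
  K <- config$K; M <- config$M
  if (N < K) warnf("fewer items (%d) than nodes (%d): map will be sparse", N, K)
  center <- colMeans(T0)
  Tc <- sweep(T0, 2, center)
  scl <- rep(1, D)
  if (isTRUE(config$scale)) {
    scl <- apply(Tc, 2, stats::sd)
    scl[scl == 0] <- 1
    Tc <- sweep(Tc, 2, scl, "/")
  }

  nodes <- latent_grid(config$k_side)
  centers <- latent_grid(config$m_side)
  spacing <- if (config$m_side > 1) 2 / (config$m_side - 1) else 2
  sigma <- config$rbf_width_factor * spacing
  Phi <- gtm_basis(nodes, centers, sigma)
  P <- ncol(Phi)                     # M + 3 (RBFs, linear x2, bias)
  reg_mask <- c(rep(1, P - 1), 0)    # no decay on the bias row

  # deterministic PCA initialization
  sv <- svd(Tc, nu = 0, nv = min(3, D))
  V <- sv$v
  for (j in seq_len(ncol(V))) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  ev <- sv$d^2 / N                   # PC variances
  sdx <- apply(nodes, 2, stats::sd)
  Xs <- sweep(nodes, 2, sqrt(ev[1:2]) / pmax(sdx, 1e-12), "*")
  Y0 <- Xs %*% t(V[, 1:2, drop = FALSE])
  W <- solve(crossprod(Phi) + 1e-10 * diag(P), crossprod(Phi, Y0))
  Y <- Phi %*% W
  nn <- cross_dist2(Y, Y); diag(nn) <- Inf
  grid_var <- mean(sqrt(apply(nn, 1, min)))^2 / 4
  var3 <- if (length(ev) >= 3 && D > 2) ev[3] else 0
  beta <- 1 / max(var3, grid_var, 1e-12)

  lambda <- config$regularization
  ll_trace <- numeric(0)
  obj_trace <- numeric(0)     # penalized objective: LL - (lambda/2)||W_reg||^2
  obj_old <- -Inf
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    D2 <- cross_dist2(Y, Tc)                       # K x N
    lr <- -beta / 2 * D2
    mx <- apply(lr, 2, max)
    lse <- mx + log(colSums(exp(sweep(lr, 2, mx))))
    ll <- sum(lse) + N * (D / 2 * log(beta / (2 * pi)) - log(K))
    obj <- ll - lambda / 2 * sum((W * reg_mask)^2)
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj) && is.finite(obj_old) &&
        abs(obj - obj_old) < config$ll_tolerance * abs(obj_old)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
    R <- exp(sweep(lr, 2, lse))                    # K x N, columns sum to 1
    G <- rowSums(R)
    A <- crossprod(Phi, Phi * G) + (lambda / beta) * diag(reg_mask)
    B <- crossprod(Phi, R %*% Tc)
    W <- tryCatch(solve(A, B), error = function(e) {
      warnf("singular M-step system: solving with ridge fallback")
      solve(A + 1e-8 * mean(diag(A)) * diag(P), B)
    })
    Y <- Phi %*% W
    res <- sum(exp(sweep(lr, 2, lse)) * cross_dist2(Y, Tc))
    beta <- min(N * D / max(res, 1e-300), 1e12)
  }
  structure(list(config = config, nodes = nodes, rbf_centers = centers,
                 sigma = sigma, Phi = Phi, W = W, noise_precision = beta,
                 center = center, scale = scl, scaled = isTRUE(config$scale),
                 D = D, ll_trace = ll_trace, objective_trace = obj_trace,
                 converged = converged, n_train = N),
            class = "GTMModel")
}

#' @export
print.GTMModel <- function(x, ...) {
  cat(sprintf("GTMModel: %d nodes (%dx%d), %d RBFs, D=%d, beta=%.4g, %d EM iterations%s\n",
              x$config$K, x$config$k_side, x$config$k_side, x$config$M, x$D,
              x$noise_precision, length(x$ll_trace),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

# Center/scale new data with the model's training record.
gtm_transform <- function(model, data) {
  X <- as.matrix(data)
  if (ncol(X) != model$D)
    stopf("data has %d columns, model expects %d", ncol(X), model$D)
  X <- sweep(X, 2, model$center)
  if (model$scaled) X <- sweep(X, 2, model$scale, "/")
  X
}

#' Node manifold images of a fitted model
#' @param model a [fit_gtm()] model.
#' @return K x D matrix of node images in (centered/scaled) data space.
#' @export
gtm_node_images <- function(model) model$Phi %*% model$W

#' Responsibilities of descriptor vectors on a fitted map
#'
#' `R_nk` is the posterior probability that item n is generated by node k
#' (softmax over nodes of `-beta/2 ||y_k - t_n||^2`); every row sums to 1.
#'
#' @param model a [fit_gtm()] model.
#' @param data N x D matrix in the model's descriptor space.
#' @return N x K responsibility matrix (rows = items).
#' @export
responsibilities <- function(model, data) {
  X <- gtm_transform(model, data)
  Y <- gtm_node_images(model)
  lr <- -model$noise_precision / 2 * cross_dist2(Y, X)   # K x N
  mx <- apply(lr, 2, max)
  lse <- mx + log(colSums(exp(sweep(lr, 2, mx))))
  R <- t(exp(sweep(lr, 2, lse)))
  rownames(R) <- rownames(data)
  R
}

#' Cumulated responsibility of an item subset
#'
#' `CR_k = sum_{n in subset} R_nk`; the total over nodes equals the subset
#' size (responsibility conservation).
#'
#' @param R N x K responsibility matrix.
#' @param subset item indices (or logical mask); empty gives a zero vector
#'   with a warning.
#' @return K-vector of cumulated responsibilities.
#' @export
cumulated_responsibility <- function(R, subset = seq_len(nrow(R))) {
  Rs <- R[subset, , drop = FALSE]
  if (!nrow(Rs)) {
    warnf("empty subset: zero cumulated responsibility")
    return(numeric(ncol(R)))
  }
  colSums(Rs)
}

#' Residual of data off the fitted manifold's affine span
#'
#' Distance of each (centered) data point from the affine subspace spanned
#' by the node images.  For data lying on an affine plane this measures how
#' exactly the manifold captured the plane.
#'
#' @param model a [fit_gtm()] model.
#' @param data N x D matrix.
#' @return per-point residual norms.
#' @export
gtm_reconstruction_error <- function(model, data) {
  X <- gtm_transform(model, data)
  Y <- gtm_node_images(model)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  sv <- svd(Yc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  V <- sv$v[, seq_len(rank), drop = FALSE]
  Xc <- sweep(X, 2, mu)
  resid <- Xc - Xc %*% V %*% t(V)
  sqrt(rowSums(resid^2))
}

#' Sample synthetic data from a fitted GTM
#'
#' Draws nodes uniformly and adds isotropic Gaussian noise at the model's
#' noise precision (or an override), returning data in the original
#' descriptor space.  Used for parameter-recovery checks.
#'
#' @param model a [fit_gtm()] model.
#' @param n number of samples.
#' @param noise_sd noise standard deviation; default `1/sqrt(noise_precision)`.
#' @param seed integer seed.
#' @return n x D matrix.
#' @export
sample_gtm <- function(model, n, noise_sd = NULL, seed = 1) {
  if (is.null(noise_sd)) noise_sd <- 1 / sqrt(model$noise_precision)
  Y <- gtm_node_images(model)
  with_seed(seed, {
    k <- sample.int(nrow(Y), n, replace = TRUE)
    X <- Y[k, , drop = FALSE] +
      matrix(stats::rnorm(n * ncol(Y), sd = noise_sd), n)
    if (model$scaled) X <- sweep(X, 2, model$scale, "*")
    sweep(X, 2, model$center, "+")
  })
}

#' Serialize a GTM model to JSON
#'
#' Stores config, weights, noise precision and the centering record; the
#' basis is rebuilt from the config on load, so maps are portable text
#' artifacts.
#'
#' @param model a [fit_gtm()] model.
#' @param path output path.
#' @export
write_gtm <- function(model, path) {
  obj <- list(config = unclass(model$config), W = model$W,
              noise_precision = model$noise_precision,
              center = model$center, scale = model$scale,
              scaled = model$scaled, D = model$D,
              ll_trace = model$ll_trace, converged = model$converged,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a GTM model written by [write_gtm()]
#' @param path JSON path.
#' @return a `GTMModel`.
#' @export
read_gtm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(gtm_config, o$config[c("k_side", "m_side", "rbf_width_factor",
                                        "regularization", "max_iter",
                                        "ll_tolerance", "scale", "seed")])
  nodes <- latent_grid(cfg$k_side)
  centers <- latent_grid(cfg$m_side)
  spacing <- if (cfg$m_side > 1) 2 / (cfg$m_side - 1) else 2
  sigma <- cfg$rbf_width_factor * spacing
  structure(list(config = cfg, nodes = nodes, rbf_centers = centers,
                 sigma = sigma, Phi = gtm_basis(nodes, centers, sigma),
                 W = matrix(o$W, ncol = o$D), noise_precision = o$noise_precision,
                 center = o$center, scale = o$scale, scaled = o$scaled,
                 D = o$D, ll_trace = o$ll_trace, converged = o$converged,
                 n_train = o$n_train),
            class = "GTMModel")
}
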