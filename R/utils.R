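# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are deterministic without
#' disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-seed derived from a master seed and a stream name.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, name) {
  v <- as.numeric(utf8ToInt(name))
  h <- sum(v * seq_along(v) * 2654435) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Squared Euclidean cross-distance matrix between rows of A (n x d) and B (m x d).
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Format numerics for CSV output with a fixed significant-digit budget so
# repeated runs are byte-identical.
fmt_num <- function(x, digits = 12) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "g"), x))
}
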