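## Class balancing: random undersampling of the major class, or SMOTE
## oversampling of the minor class. SMOTE is intended to run in the
## assembled, z-scored feature space so Euclidean neighborhoods are
## scale-meaningful.

balanced_set <- function(X, y, method, seed, synthetic) {
  stopifnot(nrow(X) == length(y), length(synthetic) == length(y))
  structure(list(X = X, y = as.integer(y), method = method,
                 seed = as.integer(seed), synthetic = synthetic,
                 n_synthetic = sum(synthetic)),
            class = "balanced_set")
}

#' @export
print.balanced_set <- function(x, ...) {
  cat("Balanced set (", x$method, "): ", sum(x$y == 0), " / ", sum(x$y == 1),
      " per class; ", x$n_synthetic, " synthetic rows (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2)
    stop("balancing requires both classes to be present")
}

#' Random undersampling of the majority class
#'
#' Keeps every minority row and a seeded uniform random subset (without
#' replacement) of majority rows of equal size; the result's row order is
#' shuffled deterministically by the seed.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1), one per row of `X`.
#' @param seed integer RNG seed.
#' @return `"balanced_set"` with equal class counts and no synthetic rows.
#' @export
undersample <- function(X, y, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  check_two_classes(y)
  tab <- table(factor(y, levels = c(0, 1)))
  minor <- as.integer(names(tab)[which.min(tab)])
  keep_minor <- which(y == minor)
  pool_major <- which(y != minor)
  with_seed(seed, {
    keep_major <- sample(pool_major, length(keep_minor), replace = FALSE)
    idx <- sample(c(keep_minor, keep_major))
  })
  balanced_set(X[idx, , drop = FALSE], y[idx], "undersample", seed,
               synthetic = rep(FALSE, length(idx)))
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic Minority Over-sampling TEchnique: each synthetic point is
#' `x + u * (z - x)` where `x` is a uniformly chosen minority row, `z` one
#' of its k nearest minority neighbors (Euclidean), and `u ~ Uniform(0,1)`.
#' Points are generated until the classes are equal. Existing rows are
#' never modified; synthetic rows are flagged.
#'
#' @param X numeric feature matrix (z-scored features recommended).
#' @param y binary labels (0/1).
#' @param k_neighbors neighborhood size (default 5; effectively
#'   `min(k_neighbors, minority size - 1)`).
#' @param seed integer RNG seed.
#' @return `"balanced_set"` with equal class counts; `synthetic` flags the
#'   generated rows (appended after the originals).
#' @export
smote <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  check_two_classes(y)
  stopifnot(k_neighbors >= 1)
  tab <- table(factor(y, levels = c(0, 1)))
  minor <- as.integer(names(tab)[which.min(tab)])
  idx_min <- which(y == minor)
  n_needed <- max(tab) - min(tab)
  if (length(idx_min) < 2)
    stop("SMOTE needs at least 2 minority rows (no line segments exist)")
  if (n_needed == 0)
    return(balanced_set(X, y, "smote", seed, rep(FALSE, length(y))))
  Xm <- X[idx_min, , drop = FALSE]
  k_eff <- min(k_neighbors, nrow(Xm) - 1L)
  ## k nearest minority neighbors of each minority row (self excluded)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- matrix(0L, nrow(Xm), k_eff)
  for (i in seq_len(nrow(Xm))) nn[i, ] <- order(d[i, ])[seq_len(k_eff)]
  synth <- with_seed(seed, {
    base_idx <- sample(nrow(Xm), n_needed, replace = TRUE)
    nb_pick <- sample.int(k_eff, n_needed, replace = TRUE)
    u <- runif(n_needed)
    Xm[base_idx, , drop = FALSE] +
      u * (Xm[nn[cbind(base_idx, nb_pick)], , drop = FALSE] -
             Xm[base_idx, , drop = FALSE])
  })
  balanced_set(rbind(X, synth), c(y, rep(minor, n_needed)), "smote", seed,
               synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_needed)))
}
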