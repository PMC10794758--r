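## k-mer composition features with PCA reduction.
##
## Overlapping dinucleotide (16-D) and trinucleotide (64-D) frequency
## vectors, reduced by PCA fit on training rows only. Frequencies rather
## than raw counts enter the PCA so that sequence length is not a confound.

#' Overlapping k-mer frequency vector
#'
#' Counts overlapping N-free k-mer windows and normalizes to a probability
#' vector over the 4^k k-mers.
#'
#' @param seq a single normalized sequence.
#' @param k k-mer order (2 or 3 in the pipeline; any k >= 1 accepted).
#' @return named numeric vector of length 4^k summing to 1.
#' @export
composition_vector <- function(seq, k) {
  counts <- kmer_counts(seq, k)
  total <- sum(counts)
  if (total == 0) stop("no N-free ", k, "-mer in sequence")
  counts / total
}

#' k-mer frequency matrix for a sequence set
#'
#' @param records sequence-set data.frame.
#' @param k k-mer order.
#' @return numeric matrix, one row per record (rownames = ids), 4^k columns.
#' @export
composition_matrix <- function(records, k) {
  m <- t(vapply(seq_len(nrow(records)), function(i) {
    tryCatch(composition_vector(records$seq[i], k),
             error = function(e) stop("record '", records$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(4^k)))
  rownames(m) <- records$id
  m
}

#' Fit PCA on composition rows
#'
#' Mean-centered PCA via singular value decomposition of the centered
#' matrix. Components are sorted by decreasing explained variance; if
#' `n_components` exceeds the matrix rank the trailing components carry
#' zero explained variance (with a warning). Sign convention for
#' reproducibility: in every component the loading of largest absolute
#' value is positive.
#'
#' @param x numeric matrix (rows = sequences, columns = 4^k frequencies).
#' @param n_components number of components to keep (default 15).
#' @return object of class `"kmer_pca"`: list with `mean`, `components`
#'   (n_components x p loading matrix, rows orthonormal),
#'   `explained_variance_ratio`, `n_components`, `dim`.
#' @export
fit_pca <- function(x, n_components = 15L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= n_components, n_components <= ncol(x), n_components >= 1)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  ev <- sv$d^2 / (nrow(x) - 1) # variances along all principal axes
  total_var <- sum(ev)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_components > rank)
    warning("n_components (", n_components, ") exceeds data rank (", rank,
            "); trailing components have zero explained variance")
  comp <- t(sv$v[, seq_len(n_components), drop = FALSE])
  ## deterministic sign: largest-|loading| entry of each component positive
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  evr <- if (total_var > 0) ev[seq_len(n_components)] / total_var
         else rep(0, n_components)
  evr[seq_len(n_components) > rank] <- 0
  structure(list(mean = mu, components = comp,
                 explained_variance_ratio = evr,
                 n_components = as.integer(n_components), dim = ncol(x)),
            class = "kmer_pca")
}

#' @export
print.kmer_pca <- function(x, ...) {
  cat("k-mer composition PCA: ", x$dim, " -> ", x$n_components, " components\n",
      sep = "")
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", head(x$explained_variance_ratio, 6)), collapse = " "),
      if (x$n_components > 6) "..." else "", "\n")
  cat("  cumulative:", sprintf("%.4f", sum(x$explained_variance_ratio)), "\n")
  invisible(x)
}

#' Project composition rows onto a fitted PCA
#'
#' Scores are `(x - mean) %*% t(components)`. Columns are named
#' `<prefix>_pc1`, `<prefix>_pc2`, ... in decreasing explained-variance
#' order, so taking the first j columns keeps the top-variance components.
#'
#' @param object fitted `"kmer_pca"`.
#' @param x matrix with the same column count the model was fit on.
#' @param prefix column-name prefix, e.g. `"dc"` or `"tc"`.
#' @param ... unused.
#' @return score matrix (rows x n_components).
#' @export
predict.kmer_pca <- function(object, x, prefix = "pc", ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$dim)
    stop("dimension mismatch: model fit on ", object$dim, " columns, got ", ncol(x))
  scores <- sweep(x, 2, object$mean) %*% t(object$components)
  colnames(scores) <- paste0(prefix, "_pc", seq_len(object$n_components))
  scores
}

#' PCA-reduced composition features for train/test sequence sets
#'
#' Fits one PCA per k on the TRAINING rows only (classes pooled) and
#' projects both sets with the frozen models, preventing information
#' leakage from evaluation data. Warns when a fitted PCA retains less
#' than 95 percent of the composition variance.
#'
#' @param train training sequence set.
#' @param test optional evaluation sequence set (transformed only).
#' @param n_components components per k (default 15).
#' @return list with feature-matrix data.frames `dc_train`, `tc_train`,
#'   `dc_test`, `tc_test` (NULL when `test` is NULL) and fitted models
#'   `dc_model`, `tc_model`.
#' @export
composition_features <- function(train, test = NULL, n_components = 15L) {
  out <- list()
  for (spec in list(list(k = 2L, prefix = "dc"), list(k = 3L, prefix = "tc"))) {
    xtr <- composition_matrix(train, spec$k)
    model <- fit_pca(xtr, n_components)
    retained <- sum(model$explained_variance_ratio)
    if (retained < 0.95)
      warning(sprintf("%s PCA retains %.1f%% of variance (< 95%%)",
                      toupper(spec$prefix), 100 * retained))
    score_df <- function(records, x) {
      s <- predict(model, x, prefix = spec$prefix)
      cbind(data.frame(id = records$id, label = records$label,
                       stringsAsFactors = FALSE), as.data.frame(s))
    }
    out[[paste0(spec$prefix, "_model")]] <- model
    out[[paste0(spec$prefix, "_train")]] <- score_df(train, xtr)
    out[[paste0(spec$prefix, "_test")]] <-
      if (is.null(test)) NULL else score_df(test, composition_matrix(test, spec$k))
  }
  out
}
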