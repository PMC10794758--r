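## Classification metrics and distribution fitting.
##
## Six threshold/ranking metrics from predicted probabilities (positive
## class = mRNA, label 1), plus maximum-likelihood fits of the lognormal,
## gamma and exponential families to positive-valued feature distributions
## (period-3 peak, SNR) with AIC model selection.

#' Classification metrics from probabilities
#'
#' Accuracy, precision, recall and F1 come from the confusion table at the
#' given threshold (predicted positive when probability exceeds it);
#' ROC-AUC by trapezoidal integration of the ROC curve over all score
#' thresholds (equal to the Mann-Whitney probability with ties counting
#' one half); PRC-AUC by the step-interpolated average-precision
#' convention, which avoids the optimism of trapezoidal interpolation in
#' precision-recall space. Undefined precision (no positive predictions)
#' is recorded as 0 with a warning flag.
#'
#' @param y_true binary labels (0 = lncRNA, 1 = mRNA).
#' @param y_prob predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `"metrics_report"`: list with `accuracy`,
#'   `precision`, `recall`, `roc_auc`, `prc_auc`, `f1`, `confusion`
#'   (2x2 integer table), `threshold`, `precision_undefined`.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  stopifnot(all(y_true %in% 0:1), all(y_prob >= 0 & y_prob <= 1))
  pred <- as.integer(y_prob > threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  accuracy <- (tp + tn) / length(y_true)
  precision_undefined <- (tp + fp) == 0
  if (precision_undefined) warning("no positive predictions; precision recorded as 0")
  precision <- if (precision_undefined) 0 else tp / (tp + fp)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 roc_auc = roc_auc(y_true, y_prob),
                 prc_auc = prc_auc(y_true, y_prob), f1 = f1,
                 confusion = confusion, threshold = threshold,
                 precision_undefined = precision_undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (positive class = mRNA, threshold ",
      x$threshold, ")\n", sep = "")
  for (m in c("accuracy", "precision", "recall", "roc_auc", "prc_auc", "f1"))
    cat(sprintf("  %-9s %.4f\n", m, x[[m]]))
  cat("  confusion (rows = truth 0/1, cols = pred 0/1):\n")
  print(x$confusion)
  invisible(x)
}

#' ROC area under the curve
#'
#' Trapezoidal integration of the (FPR, TPR) curve traced over all
#' distinct score thresholds, from (0,0) to (1,1).
#'
#' @param y_true binary labels.
#' @param y_score real-valued scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("ROC-AUC needs both classes")
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]; s <- y_score[ord]
  ## cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  fp <- cumsum(y == 0)[last_of_tie]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Precision-recall area (average precision)
#'
#' Step interpolation: `AP = sum_k (R_k - R_{k-1}) P_k` over thresholds in
#' decreasing score order.
#'
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`.
#' @export
prc_auc <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1)
  if (n_pos == 0) stop("PRC-AUC needs positive examples")
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]; s <- y_score[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  n_pred <- seq_along(y)[last_of_tie]
  precision <- tp / n_pred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Maximum-likelihood fit of one distribution family
#'
#' Closed forms for the exponential (`rate = 1/mean`) and lognormal
#' (`meanlog` = mean of logs, `sdlog` = MLE standard deviation of logs,
#' n denominator); the gamma shape solves
#' `log(shape) - digamma(shape) = log(mean) - mean(log x)` by Newton
#' iteration (tolerance 1e-10, at most 200 iterations), with
#' `rate = shape/mean`. Degenerate samples with zero log-variance are an
#' error for the lognormal and gamma families (their densities collapse);
#' the exponential closed form still applies.
#'
#' @param samples positive reals, length >= 2.
#' @param family `"lognormal"`, `"gamma"` or `"exponential"`.
#' @return object of class `"dist_fit"`: list with `family`, `params`
#'   (named vector), `loglik`, `aic`, `n`.
#' @export
fit_distribution <- function(samples, family = c("lognormal", "gamma", "exponential")) {
  family <- match.arg(family)
  x <- as.numeric(samples)
  if (any(x <= 0)) stop("samples must be strictly positive")
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  lx <- log(x)
  if (family == "exponential") {
    rate <- 1 / mean(x)
    params <- c(rate = rate)
    loglik <- sum(dexp(x, rate = rate, log = TRUE))
  } else if (family == "lognormal") {
    mu <- mean(lx)
    s2 <- mean((lx - mu)^2)
    if (s2 == 0) stop("degenerate sample: zero variance of logs")
    params <- c(meanlog = mu, sdlog = sqrt(s2))
    loglik <- sum(dlnorm(x, meanlog = mu, sdlog = sqrt(s2), log = TRUE))
  } else {
    s <- log(mean(x)) - mean(lx) # >= 0 by Jensen; 0 only for constant samples
    if (s <= 0) stop("degenerate sample: zero variance of logs")
    shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (it in seq_len(200)) {
      delta <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
      shape_new <- shape - delta
      if (shape_new <= 0) shape_new <- shape / 2
      if (abs(shape_new - shape) < 1e-10 * max(1, shape)) { shape <- shape_new; break }
      shape <- shape_new
      if (it == 200) stop("gamma MLE did not converge in 200 iterations")
    }
    rate <- shape / mean(x)
    params <- c(shape = shape, rate = rate)
    loglik <- sum(dgamma(x, shape = shape, rate = rate, log = TRUE))
  }
  n_par <- length(params)
  structure(list(family = family, params = params, loglik = loglik,
                 aic = 2 * n_par - 2 * loglik, n = n),
            class = "dist_fit")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat("MLE fit: ", x$family, " (n = ", x$n, ")\n", sep = "")
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  loglik = %.4f, AIC = %.4f\n", x$loglik, x$aic))
  invisible(x)
}

#' Fit all three families and select by AIC
#'
#' Fits lognormal, gamma and exponential by maximum likelihood and selects
#' the family with minimal AIC, breaking ties toward fewer parameters.
#' Non-positive values (e.g. the zero SNR of a homopolymer) are excluded
#' with a message, since all three families have positive support.
#'
#' @param samples numeric vector.
#' @return object of class `"dist_fit_table"`: list with `fits` (named
#'   list of `"dist_fit"`), `best` (selected family name), `aic` (named
#'   vector), `n_excluded`.
#' @export
select_best_fit <- function(samples) {
  x <- as.numeric(samples)
  n_excluded <- sum(x <= 0)
  if (n_excluded > 0) {
    message(n_excluded, " non-positive value(s) excluded from distribution fitting")
    x <- x[x > 0]
  }
  fits <- lapply(stats::setNames(nm = c("lognormal", "gamma", "exponential")),
                 function(f) fit_distribution(x, f))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  n_par <- vapply(fits, function(f) length(f$params), numeric(1))
  best <- names(aic)[order(aic, n_par)][1]
  structure(list(fits = fits, best = best, aic = aic, n_excluded = n_excluded),
            class = "dist_fit_table")
}

#' @export
print.dist_fit_table <- function(x, ...) {
  cat("Distribution fits (AIC model selection):\n")
  for (f in names(x$fits))
    cat(sprintf("  %-12s AIC = %.2f%s\n", f, x$aic[[f]],
                if (f == x$best) "  <- selected" else ""))
  if (x$n_excluded > 0) cat("  (", x$n_excluded, " non-positive values excluded)\n")
  invisible(x)
}

#' Write a distribution-fit table as TSV
#'
#' @param table a `"dist_fit_table"`.
#' @param path output path.
#' @export
write_distfit_tsv <- function(table, path) {
  rows <- lapply(table$fits, function(f) {
    data.frame(family = f$family,
               params = paste(sprintf("%s=%.8g", names(f$params), f$params),
                              collapse = ";"),
               loglik = f$loglik, aic = f$aic, n = f$n,
               selected = f$family == table$best)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
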