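## A small feed-forward binary classifier trained with binary cross-entropy
## by seeded mini-batch gradient descent. Input widths in this pipeline
## range from 2 to 15 columns, so one configurable hidden layer of width
## max(8, 2 * input_dim) covers the regime; everything is exposed in the
## config.

#' Network/training configuration
#'
#' @param input_dim number of input features.
#' @param hidden_layers integer vector of hidden widths; default one layer
#'   of width `max(8, 2 * input_dim)`.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param epochs training epochs (default 200).
#' @param batch_size mini-batch size (default 32).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return list of class `"mlp_config"`.
#' @export
mlp_config <- function(input_dim, hidden_layers = NULL,
                       activation = c("relu", "tanh"),
                       learning_rate = 0.01, epochs = 200L, batch_size = 32L,
                       seed = 1L) {
  activation <- match.arg(activation)
  if (is.null(hidden_layers)) hidden_layers <- max(8L, 2L * input_dim)
  stopifnot(input_dim >= 1, all(hidden_layers >= 1), learning_rate > 0,
            epochs >= 1, batch_size >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_layers = as.integer(hidden_layers),
                 activation = activation, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Binary cross-entropy loss
#'
#' `mean(-y * log(p) - (1 - y) * log(1 - p))` with predictions clipped to
#' `[eps, 1 - eps]` so the logs stay finite.
#'
#' @param y_true binary labels.
#' @param y_pred predicted probabilities.
#' @param eps clipping bound (default 1e-12).
#' @return nonnegative scalar.
#' @export
bce_loss <- function(y_true, y_pred, eps = 1e-12) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  mean(-y_true * log(p) - (1 - y_true) * log(1 - p))
}

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
    tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Glorot-uniform initialization, seeded.
init_weights <- function(config) {
  widths <- c(config$input_dim, config$hidden_layers, 1L)
  with_seed(config$seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1]))
      list(W = matrix(runif(widths[l] * widths[l + 1], -lim, lim),
                      widths[l], widths[l + 1]),
           b = rep(0, widths[l + 1]))
    })
  })
}

## Forward pass; returns per-layer pre-activations and activations.
mlp_forward <- function(weights, X, activation) {
  act <- activation_fun(activation)
  L <- length(weights)
  zs <- as <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, `+`)
    a <- if (l < L) act$f(z) else sigmoid(z)
    zs[[l]] <- z; as[[l]] <- a
  }
  list(z = zs, a = as, p = as.vector(as[[L]]))
}

## Analytic gradients of the mean BCE loss w.r.t. all weights and biases.
mlp_gradients <- function(weights, X, y, activation) {
  act <- activation_fun(activation)
  fw <- mlp_forward(weights, X, activation)
  L <- length(weights)
  n <- nrow(X)
  grads <- vector("list", L)
  ## output delta: sigmoid + BCE cancel to (p - y) / n
  delta <- matrix((fw$p - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1) X else fw$a[[l - 1]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1) delta <- (delta %*% t(weights[[l]]$W)) * act$df(fw$z[[l - 1]])
  }
  list(grads = grads, loss = bce_loss(y, fw$p))
}

#' Fit the neural classifier
#'
#' Mini-batch gradient descent on the binary cross-entropy loss;
#' deterministic given `config$seed`. Columns are z-scored with
#' training-set statistics unless a pre-computed `scaler` is supplied (in
#' which case `x` is assumed already scaled); the scaler is stored in the
#' model and applied automatically at prediction time.
#'
#' @param x numeric feature matrix (rows = sequences).
#' @param y binary labels (0 = lncRNA, 1 = mRNA), both classes present
#'   with at least 2 rows each.
#' @param config an [mlp_config()]; default configuration if omitted.
#' @param scaler optional list `(center, scale)` from [scaler_fit()].
#' @return object of class `"lnc_mlp"`: list with `config`, `weights`,
#'   `scaler`, `loss_history` (one mean training loss per epoch) and
#'   `feature_names`.
#' @export
mlp_fit <- function(x, y, config = NULL, scaler = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  if (any(!is.finite(x))) stop("non-finite values in feature matrix")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (min(table(factor(y, levels = c(0, 1)))) < 2)
    stop("need at least 2 rows per class")
  if (is.null(config)) config <- mlp_config(input_dim = ncol(x))
  stopifnot(config$input_dim == ncol(x))
  if (is.null(scaler)) {
    scaler <- scaler_fit(x)
    x <- scaler_apply(scaler, x)
  }
  weights <- init_weights(config)
  n <- nrow(x)
  loss_history <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        g <- mlp_gradients(weights, x[idx, , drop = FALSE], y[idx],
                           config$activation)
        for (l in seq_along(weights)) {
          weights[[l]]$W <- weights[[l]]$W - config$learning_rate * g$grads[[l]]$W
          weights[[l]]$b <- weights[[l]]$b - config$learning_rate * g$grads[[l]]$b
        }
        batch_losses[bi] <- g$loss
      }
      loss_history[epoch] <- mean(batch_losses)
    }
  })
  structure(list(config = config, weights = weights, scaler = scaler,
                 loss_history = loss_history,
                 feature_names = colnames(x)),
            class = "lnc_mlp")
}

#' Training-set column scaler
#'
#' @param x numeric matrix.
#' @return list `(center, scale)`; zero-variance columns get scale 1.
#' @export
scaler_fit <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, sd)
  list(center = colMeans(x), scale = ifelse(s > 0, s, 1))
}

#' @rdname scaler_fit
#' @param scaler list from `scaler_fit`.
#' @export
scaler_apply <- function(scaler, x) {
  scale(as.matrix(x), center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

#' Predict from a fitted neural classifier
#'
#' @param object fitted `"lnc_mlp"`.
#' @param x feature matrix with `config$input_dim` columns (unscaled; the
#'   stored scaler is applied).
#' @param type `"prob"` for sigmoid probabilities of the positive class
#'   (mRNA), `"class"` for thresholded 0/1 labels.
#' @param threshold decision threshold for `type = "class"` (label 1 when
#'   probability exceeds it).
#' @param ... unused.
#' @return numeric vector of probabilities or integer labels.
#' @export
predict.lnc_mlp <- function(object, x, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$config$input_dim)
    stop("dimension mismatch: model expects ", object$config$input_dim,
         " columns, got ", ncol(x))
  x <- scaler_apply(object$scaler, x)
  p <- mlp_forward(object$weights, x, object$config$activation)$p
  if (type == "prob") p else as.integer(p > threshold)
}

#' @export
print.lnc_mlp <- function(x, ...) {
  widths <- c(x$config$input_dim, x$config$hidden_layers, 1L)
  cat("Feed-forward binary classifier (", paste(widths, collapse = "-"),
      ", ", x$config$activation, " hidden, sigmoid output)\n", sep = "")
  cat("  trained ", x$config$epochs, " epochs, final BCE loss ",
      sprintf("%.4f", tail(x$loss_history, 1)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lnc_mlp <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$weights,
                      function(w) length(w$W) + length(w$b), numeric(1)))
  cat("  parameters:", n_par, "\n")
  cat("  loss: initial ", sprintf("%.4f", object$loss_history[1]),
      " -> final ", sprintf("%.4f", tail(object$loss_history, 1)), "\n", sep = "")
  invisible(object)
}

#' @export
plot.lnc_mlp <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "training BCE loss",
       main = "Training loss", ...)
  invisible(x)
}
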