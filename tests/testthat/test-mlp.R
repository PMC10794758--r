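test_that("binary cross-entropy matches direct evaluation of the formula", {
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-10)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-12)
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(bce_loss(1, 0)))
  expect_error(bce_loss(c(1, 0), 0.5), "length mismatch")
})

test_that("analytic gradients match central finite differences (2-4-1 net)", {
  cfg <- mlp_config(input_dim = 2, hidden_layers = 4, seed = 3)
  w <- lncsig:::init_weights(cfg)
  set.seed(30)
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1, 0, 1, 1, 0)
  g <- lncsig:::mlp_gradients(w, X, y, "relu")$grads
  eps <- 1e-6
  loss_at <- function(w) bce_loss(y, lncsig:::mlp_forward(w, X, "relu")$p)
  for (l in seq_along(w)) {
    for (idx in seq_along(w[[l]]$W)) {
      wp <- w; wp[[l]]$W[idx] <- wp[[l]]$W[idx] + eps
      wm <- w; wm[[l]]$W[idx] <- wm[[l]]$W[idx] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(g[[l]]$W[idx], num, tolerance = 1e-5)
    }
    for (idx in seq_along(w[[l]]$b)) {
      wp <- w; wp[[l]]$b[idx] <- wp[[l]]$b[idx] + eps
      wm <- w; wm[[l]]$b[idx] <- wm[[l]]$b[idx] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(g[[l]]$b[idx], num, tolerance = 1e-5)
    }
  }
})

separable_clouds <- function(n = 500, p = 15, seed = 70) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p, -2), n, p), matrix(rnorm(n * p, 2), n, p))
  list(X = X, y = rep(c(0L, 1L), each = n))
}

test_that("training separates well-separated Gaussian clouds", {
  d <- separable_clouds()
  fit <- mlp_fit(d$X, d$y, mlp_config(input_dim = 15, epochs = 100, seed = 5))
  acc <- mean(predict(fit, d$X, type = "class") == d$y)
  expect_gte(acc, 0.99)
  # loss decreases from start to finish
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  expect_true(all(is.finite(fit$loss_history)))
})

test_that("training is deterministic given data and seed", {
  d <- separable_clouds(n = 50, p = 4, seed = 71)
  cfg <- mlp_config(input_dim = 4, epochs = 20, seed = 9)
  f1 <- mlp_fit(d$X, d$y, cfg)
  f2 <- mlp_fit(d$X, d$y, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$weights, f2$weights)
  f3 <- mlp_fit(d$X, d$y, mlp_config(input_dim = 4, epochs = 20, seed = 10))
  expect_false(identical(f1$weights, f3$weights))
})

test_that("degenerate training inputs are rejected before training", {
  d <- separable_clouds(n = 10, p = 3, seed = 72)
  expect_error(mlp_fit(d$X, rep(1L, nrow(d$X))), "per class")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(mlp_fit(bad, d$y), "non-finite")
  expect_error(mlp_fit(d$X, rep(c(0, 2), 10)), "binary")
})

test_that("prediction is a thresholded monotone sigmoid with shape checks", {
  d <- separable_clouds(n = 30, p = 2, seed = 73)
  fit <- mlp_fit(d$X, d$y, mlp_config(input_dim = 2, epochs = 30, seed = 2))
  p <- predict(fit, d$X, type = "prob")
  expect_true(all(p > 0 & p < 1))
  expect_identical(predict(fit, d$X, type = "class"), as.integer(p > 0.5))
  expect_error(predict(fit, d$X[, 1, drop = FALSE]), "dimension mismatch")

  # all-zero weights give probability exactly 1/2
  fit0 <- fit
  fit0$weights <- lapply(fit0$weights, function(w)
    list(W = w$W * 0, b = w$b * 0))
  expect_equal(predict(fit0, d$X, type = "prob"), rep(0.5, nrow(d$X)))

  # 1-feature positive-weight network is increasing in its input
  cfg1 <- mlp_config(input_dim = 1, hidden_layers = 1, seed = 1)
  w1 <- list(list(W = matrix(1), b = 0), list(W = matrix(1), b = 0))
  fit1 <- structure(list(config = cfg1, weights = w1,
                         scaler = list(center = 0, scale = 1),
                         loss_history = 0, feature_names = "x"),
                    class = "lnc_mlp")
  ps <- predict(fit1, matrix(seq(0.1, 3, length.out = 9)), type = "prob")
  expect_true(all(diff(ps) > 0))
})

test_that("stratified split preserves the class ratio within one sample", {
  y <- rep(c(0L, 1L), c(75, 25))
  sp <- stratified_split(y, 0.8, seed = 4)
  expect_equal(sum(y[sp$train] == 0), 60)
  expect_equal(sum(y[sp$train] == 1), 20)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  # odd counts: off by at most one sample from the exact ratio
  y2 <- rep(c(0L, 1L), c(33, 11))
  sp2 <- stratified_split(y2, 0.8, seed = 4)
  expect_lte(abs(sum(y2[sp2$train] == 0) - 0.8 * 33), 1)
  expect_lte(abs(sum(y2[sp2$train] == 1) - 0.8 * 11), 1)
})
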