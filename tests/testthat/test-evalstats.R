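test_that("threshold metrics reproduce hand arithmetic on a fixed confusion", {
  # TP 40, FP 10, FN 20, TN 30
  y <- rep(c(1, 1, 0, 0), c(40, 20, 10, 30))
  p <- rep(c(0.9, 0.1, 0.9, 0.1), c(40, 20, 10, 30))
  m <- classification_metrics(y, p)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-9)
  expect_equal(m$f1, 0.727273, tolerance = 1e-6)
  expect_equal(as.integer(m$confusion), c(30L, 10L, 20L, 40L)) # tn fp fn tp
  expect_equal(sum(m$confusion), 100)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
})

test_that("perfect separation scores 1 on all six metrics", {
  y <- rep(c(1, 0), c(25, 25))
  p <- rep(c(0.9, 0.1), c(25, 25))
  m <- classification_metrics(y, p)
  for (metric in c("accuracy", "precision", "recall", "roc_auc", "prc_auc", "f1"))
    expect_equal(m[[metric]], 1.0, label = metric)
})

test_that("undefined precision is recorded as 0 with a warning", {
  y <- c(1, 1, 0)
  p <- c(0.1, 0.2, 0.3)
  expect_warning(m <- classification_metrics(y, p), "no positive predictions")
  expect_equal(m$precision, 0)
  expect_true(m$precision_undefined)
})

test_that("trapezoidal ROC-AUC equals the Mann-Whitney oracle (with ties)", {
  set.seed(80)
  y <- rbinom(200, 1, 0.4)
  s <- round(runif(200), 2) # rounding forces ties
  expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-10)
  s2 <- rnorm(200) + y       # informative, tie-free
  expect_equal(roc_auc(y, s2), oracle_auc(y, s2), tolerance = 1e-10)
  # agreement with an established implementation
  expect_equal(roc_auc(y, s2),
               as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(81)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  s <- runif(n)
  expect_lt(abs(roc_auc(y, s) - 0.5), 3 / sqrt(n))
})

test_that("average precision follows the step-interpolation convention", {
  # ranked predictions: +, -, +, - => AP = 0.5*1 + 0.5*(2/3)
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(prc_auc(y, s), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # all-positive ranking first gives AP 1
  expect_equal(prc_auc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
})

test_that("closed-form MLEs are exact and degenerate samples error cleanly", {
  x <- rep(3.5, 10)
  fe <- fit_distribution(x, "exponential")
  expect_equal(unname(fe$params["rate"]), 1 / 3.5, tolerance = 1e-12)
  # exponential loglik at the MLE simplifies to n*(log(rate) - 1)
  expect_equal(fe$loglik, 10 * (log(1 / 3.5) - 1), tolerance = 1e-10)
  expect_equal(fe$aic, 2 - 2 * fe$loglik)
  expect_error(fit_distribution(x, "lognormal"), "degenerate")
  expect_error(fit_distribution(x, "gamma"), "degenerate")
  expect_error(fit_distribution(c(1, 1)), "degenerate")
  expect_error(fit_distribution(c(-1, 2), "exponential"), "positive")
  expect_error(fit_distribution(3, "exponential"), "at least 2")
})

test_that("MLE fits agree with an independent reference implementation", {
  set.seed(82)
  x <- rgamma(2000, shape = 2.3, rate = 0.7)
  fg <- fit_distribution(x, "gamma")
  ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(unname(fg$params["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-4)
  expect_equal(unname(fg$params["rate"]), unname(ref$estimate["rate"]),
               tolerance = 1e-4)
  expect_equal(fg$loglik, as.numeric(ref$loglik), tolerance = 1e-4)

  xl <- rlnorm(2000, 0.4, 0.8)
  fl <- fit_distribution(xl, "lognormal")
  refl <- MASS::fitdistr(xl, "lognormal")
  expect_equal(unname(fl$params), unname(refl$estimate), tolerance = 1e-6)
})

test_that("lognormal parameters are recovered within sampling error", {
  set.seed(83)
  x <- rlnorm(5000, meanlog = 1, sdlog = 0.5)
  f <- fit_distribution(x, "lognormal")
  expect_lt(abs(f$params[["meanlog"]] - 1), 0.03)  # 3*sigma/sqrt(n) = 0.021
  expect_lt(abs(f$params[["sdlog"]] - 0.5), 0.02)  # 3*sigma/sqrt(2n) = 0.015
})

test_that("AIC selection recovers the generating family", {
  set.seed(84)
  sel_ln <- suppressMessages(
    select_best_fit(rlnorm(5000, 1, 0.5)))
  expect_equal(sel_ln$best, "lognormal")
  expect_equal(sel_ln$aic[["lognormal"]],
               2 * 2 - 2 * sel_ln$fits$lognormal$loglik)
  sel_exp <- select_best_fit(rexp(5000, 2))
  expect_equal(sel_exp$best, "exponential")
  # zero SNR values (homopolymers) are excluded with a message
  expect_message(sel0 <- select_best_fit(c(0, 0, rlnorm(500, 1, 0.5))),
                 "2 non-positive")
  expect_equal(sel0$n_excluded, 2)
})

test_that("family selection is invariant to positive rescaling", {
  set.seed(85)
  for (gen in list(function(n) rlnorm(n, 0.5, 0.6), function(n) rexp(n, 1.5))) {
    x <- gen(3000)
    for (a in c(0.01, 1, 250)) {
      expect_equal(select_best_fit(a * x)$best, select_best_fit(x)$best)
    }
  }
})
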