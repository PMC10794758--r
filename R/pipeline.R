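## End-to-end classifier: features -> combination -> balancing -> MLP ->
## metrics, wrapped as one fitting function returning a classed object.

#' Stratified train/test split
#'
#' Seeded random partition preserving the class ratio within one sample.
#'
#' @param labels binary label vector.
#' @param train_frac fraction assigned to training (default 0.8).
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  with_seed(seed, {
    idx_by_class <- split(seq_along(labels), labels)
    train <- unlist(lapply(idx_by_class, function(idx) {
      sample(idx, round(length(idx) * train_frac))
    }), use.names = FALSE)
  })
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

## Per-family feature matrices for a record set, using frozen PCA models.
compute_feature_store <- function(records, di_table, tri_table,
                                  dc_model, tc_model, weighting = "empirical") {
  pc <- physchem_features(records, di_table, tri_table, weighting)
  score_df <- function(model, k, prefix) {
    s <- predict(model, composition_matrix(records, k), prefix = prefix)
    cbind(data.frame(id = records$id, label = records$label,
                     stringsAsFactors = FALSE), as.data.frame(s))
  }
  list(BP = bp_features(records),
       DP = pc[, c("id", "label", paste0("dp_", ENERGY_COLS))],
       TP = pc[, c("id", "label", paste0("tp_", ENERGY_COLS))],
       DC = score_df(dc_model, 2L, "dc"),
       TC = score_df(tc_model, 3L, "tc"))
}

#' Fit the lncRNA/mRNA classifier end to end
#'
#' Pools the two labelled sequence sets, makes a seeded stratified
#' train/test split, computes the five feature families (PCA for the
#' composition families is fit on training rows only), assembles the
#' requested feature combination, z-scores columns with training-set
#' statistics, balances the training data (evaluation rows are never
#' balanced), trains the neural classifier and evaluates the six metrics
#' on the held-out split.
#'
#' @param lnc sequence set labelled 0 (lncRNA), e.g. from
#'   `read_fasta(path, label = 0)`.
#' @param mrna sequence set labelled 1 (mRNA).
#' @param combo combination name (see [combo_registry()]) or
#'   `"combo_spec"`; default `"BPDCTC"`.
#' @param balance `"undersample"`, `"smote"` or `"none"`.
#' @param di_table,tri_table energy tables (defaults: the bundled
#'   illustrative tables, see [example_energy_table()]).
#' @param n_components PCA components fitted per composition family.
#' @param train_frac training fraction of the stratified split.
#' @param smote_k SMOTE neighborhood size.
#' @param weighting energy-feature weighting (see [energy_features()]).
#' @param seed integer seed driving split, balancing and training.
#' @param epochs,learning_rate,batch_size,hidden_layers,activation
#'   passed to [mlp_config()].
#' @return object of class `"lnc_classifier"`: list with `model`
#'   (`"lnc_mlp"`), `metrics` (`"metrics_report"` on the held-out split),
#'   `combo`, `balance`, `dc_model`, `tc_model`, `di_table`, `tri_table`,
#'   `weighting`, `split` (id vectors), `manifest`.
#' @export
lnc_classifier <- function(lnc, mrna, combo = "BPDCTC",
                           balance = c("undersample", "smote", "none"),
                           di_table = example_energy_table(2),
                           tri_table = example_energy_table(3),
                           n_components = 15L, train_frac = 0.8,
                           smote_k = 5L, weighting = "empirical", seed = 1L,
                           epochs = 200L, learning_rate = 0.01,
                           batch_size = 32L, hidden_layers = NULL,
                           activation = "relu") {
  balance <- match.arg(balance)
  if (is.character(combo)) combo <- combo_spec(combo)
  stopifnot(all(lnc$label == 0L), all(mrna$label == 1L))
  records <- rbind(lnc, mrna)
  if (anyDuplicated(records$id))
    stop("duplicate sequence ids across the two classes")
  split <- stratified_split(records$label, train_frac, seed)
  train <- records[split$train, , drop = FALSE]
  test <- records[split$test, , drop = FALSE]

  comp <- composition_features(train, n_components = n_components)
  store_train <- compute_feature_store(train, di_table, tri_table,
                                       comp$dc_model, comp$tc_model, weighting)
  store_test <- compute_feature_store(test, di_table, tri_table,
                                      comp$dc_model, comp$tc_model, weighting)

  asm_train <- assemble_features(combo, store_train)
  asm_test <- assemble_features(combo, store_test)
  feat_cols <- setdiff(names(asm_train), c("id", "label"))
  X_train <- as.matrix(asm_train[, feat_cols, drop = FALSE])
  y_train <- asm_train$label
  scaler <- scaler_fit(X_train)
  Xs_train <- scaler_apply(scaler, X_train)

  bal <- switch(balance,
    undersample = undersample(Xs_train, y_train, seed = seed),
    smote = smote(Xs_train, y_train, k_neighbors = smote_k, seed = seed),
    none = balanced_set(Xs_train, y_train, "none", seed,
                        rep(FALSE, length(y_train))))

  config <- mlp_config(input_dim = combo$total, hidden_layers = hidden_layers,
                       activation = activation, learning_rate = learning_rate,
                       epochs = epochs, batch_size = batch_size, seed = seed)
  model <- mlp_fit(bal$X, bal$y, config, scaler = scaler)
  model$feature_names <- feat_cols

  X_test <- as.matrix(asm_test[, feat_cols, drop = FALSE])
  prob_test <- predict(model, X_test, type = "prob")
  metrics <- classification_metrics(asm_test$label, prob_test)

  manifest <- list(
    combo = combo$name, balance = balance, seed = seed,
    train_frac = train_frac, n_components = n_components,
    smote_k = smote_k, weighting = weighting,
    n_train = nrow(train), n_test = nrow(test),
    n_synthetic = bal$n_synthetic,
    package_version = as.character(packageVersion("lncsig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(model = model, metrics = metrics, combo = combo,
                 balance = balance, dc_model = comp$dc_model,
                 tc_model = comp$tc_model, di_table = di_table,
                 tri_table = tri_table, weighting = weighting,
                 split = list(train_ids = train$id, test_ids = test$id),
                 manifest = manifest),
            class = "lnc_classifier")
}

#' @export
print.lnc_classifier <- function(x, ...) {
  cat("lncRNA/mRNA classifier\n")
  cat("  combination :", x$combo$name, "(", x$combo$total, "features )\n")
  cat("  balancing   :", x$balance, "\n")
  cat("  split       :", length(x$split$train_ids), "train /",
      length(x$split$test_ids), "test\n")
  cat(sprintf("  held-out    : accuracy %.4f, ROC-AUC %.4f, F1 %.4f\n",
              x$metrics$accuracy, x$metrics$roc_auc, x$metrics$f1))
  invisible(x)
}

#' @export
summary.lnc_classifier <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$metrics)
  invisible(object)
}

#' Classify new sequences with a fitted pipeline
#'
#' Recomputes the feature families for the new records with the frozen
#' PCA models and energy tables, assembles the fitted combination and
#' applies the trained network.
#'
#' @param object fitted `"lnc_classifier"`.
#' @param records sequence set (labels may be `NA`).
#' @param type `"prob"` or `"class"` (see [predict.lnc_mlp()]).
#' @param ... passed to [predict.lnc_mlp()].
#' @return probabilities or 0/1 labels, named by record id.
#' @export
predict.lnc_classifier <- function(object, records, type = "prob", ...) {
  store <- compute_feature_store(records, object$di_table, object$tri_table,
                                 object$dc_model, object$tc_model,
                                 object$weighting)
  asm <- assemble_features(object$combo, store)
  X <- as.matrix(asm[, setdiff(names(asm), c("id", "label")), drop = FALSE])
  stats::setNames(predict(object$model, X, type = type, ...), asm$id)
}

#' @export
plot.lnc_classifier <- function(x, ...) {
  plot(x$model, ...)
  invisible(x)
}
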