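## JSON serialization of a fitted pipeline, so `train` output can be
## reloaded by `predict` in another process.

pca_to_list <- function(m) {
  list(mean = m$mean, components = m$components,
       explained_variance_ratio = m$explained_variance_ratio,
       n_components = m$n_components, dim = m$dim)
}

pca_from_list <- function(l) {
  structure(list(mean = as.numeric(l$mean),
                 components = matrix(unlist(l$components),
                                     nrow = l$n_components, byrow = FALSE),
                 explained_variance_ratio = as.numeric(l$explained_variance_ratio),
                 n_components = as.integer(l$n_components),
                 dim = as.integer(l$dim)),
            class = "kmer_pca")
}

table_to_list <- function(t) {
  list(k = t$k, kmer = rownames(t$energies),
       energies = unname(t$energies))
}

table_from_list <- function(l) {
  e <- matrix(unlist(l$energies), ncol = 3, byrow = FALSE,
              dimnames = list(unlist(l$kmer), ENERGY_COLS))
  energy_table(l$k, e)
}

#' Save a fitted classifier as JSON
#'
#' @param fit a `"lnc_classifier"`.
#' @param path output path.
#' @export
save_classifier <- function(fit, path) {
  stopifnot(inherits(fit, "lnc_classifier"))
  m <- fit$model
  obj <- list(
    format = "lncsig_classifier",
    combo = fit$combo$name,
    balance = fit$balance,
    weighting = fit$weighting,
    config = unclass(m$config),
    weights = lapply(m$weights, function(w) list(W = w$W, b = w$b)),
    scaler = m$scaler,
    loss_history = m$loss_history,
    feature_names = m$feature_names,
    dc_model = pca_to_list(fit$dc_model),
    tc_model = pca_to_list(fit$tc_model),
    di_table = table_to_list(fit$di_table),
    tri_table = table_to_list(fit$tri_table),
    manifest = fit$manifest
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path JSON path.
#' @return a `"lnc_classifier"` (without the original metrics/split, which
#'   belong to the training run).
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "lncsig_classifier"))
    stop("not a saved lncsig classifier: ", path)
  cfg <- mlp_config(input_dim = obj$config$input_dim,
                    hidden_layers = obj$config$hidden_layers,
                    activation = obj$config$activation,
                    learning_rate = obj$config$learning_rate,
                    epochs = obj$config$epochs,
                    batch_size = obj$config$batch_size,
                    seed = obj$config$seed)
  weights <- lapply(obj$weights, function(w)
    list(W = as.matrix(w$W), b = as.numeric(w$b)))
  model <- structure(list(config = cfg, weights = weights,
                          scaler = list(center = as.numeric(obj$scaler$center),
                                        scale = as.numeric(obj$scaler$scale)),
                          loss_history = as.numeric(obj$loss_history),
                          feature_names = obj$feature_names),
                     class = "lnc_mlp")
  structure(list(model = model, metrics = NULL,
                 combo = combo_spec(obj$combo), balance = obj$balance,
                 dc_model = pca_from_list(obj$dc_model),
                 tc_model = pca_from_list(obj$tc_model),
                 di_table = table_from_list(obj$di_table),
                 tri_table = table_from_list(obj$tri_table),
                 weighting = obj$weighting,
                 split = NULL, manifest = obj$manifest),
            class = "lnc_classifier")
}
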