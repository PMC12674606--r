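#' Configuration of the random-projection stacking classifier
#'
#' Defaults reproduce the reference operating point: 400-dimensional
#' projections, 20 independent projection matrices, the full ten-model base
#' panel with hard-label meta-features built out-of-fold over 5 inner
#' stratified folds, and a 128-64-32-16 MLP meta-learner trained for 1000
#' epochs (batch 64, Adam at 1e-4, dropout 0.2).
#'
#' @param k Projection dimensionality per random projection, default 400.
#' @param m Number of independent random projections, default 20.
#' @param models Base-model subset (names from [rps_model_names()]).
#' @param meta_mode `"hard_labels"` (default) or `"probabilities"` —
#'   whether base models contribute predicted labels or per-class
#'   probabilities to the composite feature.
#' @param inner_folds Stratified folds for out-of-fold stacking, default 5.
#' @param hidden Meta-learner hidden-layer widths, default `c(128, 64, 32, 16)`.
#' @param epochs Meta-learner epochs, default 1000.
#' @param batch_size Meta-learner batch size, default 64.
#' @param learning_rate Adam step size, default 1e-4.
#' @param dropout Dropout rate, default 0.2.
#' @param seed Global seed; all per-component seeds are derived from it.
#' @param ... Extra arguments forwarded to [base_registry()] (e.g.
#'   `num_trees`, `nrounds`, `nn_epochs`).
#' @return An object of class `rps_config` (named list).
#' @export
rps_config <- function(k = 400, m = 20, models = rps_model_names(),
                       meta_mode = c("hard_labels", "probabilities"),
                       inner_folds = 5, hidden = c(128, 64, 32, 16),
                       epochs = 1000, batch_size = 64, learning_rate = 1e-4,
                       dropout = 0.2, seed = 1L, ...) {
  meta_mode <- match.arg(meta_mode)
  if (!is_count(k) || !is_count(m)) stopf("k and m must be positive integers")
  structure(list(k = as.integer(k), m = as.integer(m), models = models,
                 meta_mode = meta_mode, inner_folds = as.integer(inner_folds),
                 hidden = hidden, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 seed = as.integer(seed), registry_args = list(...)),
            class = c("rps_config", "list"))
}

#' Fit the random-projection stacking classifier
#'
#' The training pipeline: (1) fuse `m` independent Gaussian random
#' projections of the log-scale expression matrix into one n x (m*k)
#' feature block ([fuse_projections()]); (2) obtain leakage-safe
#' out-of-fold predictions from the heterogeneous base-model panel
#' ([oof_base_predictions()]); (3) append them to the fused features
#' ([build_composite()]); (4) train the MLP meta-learner ([fit_meta()]).
#' The returned model archives the projection seeds, the base models refit
#' on all samples, the meta-learner weights, the label set and the
#' configuration, so prediction is fully reproducible.
#'
#' @param X An `expr_matrix` (stage `"log"`) or plain numeric matrix,
#'   samples x genes with ids.
#' @param y A [label_vector()], factor or character vector of per-sample
#'   class labels.
#' @param config An [rps_config()]; the default reproduces the reference
#'   operating point.
#' @param seed Optional override of `config$seed`.
#' @return An object of class `rpstack`.
#' @examples
#' \donttest{
#' sim <- synth_generate(synth_config(n_samples = 80, n_genes = 300,
#'                                    effect_size_delta = 2, seed = 1))
#' cfg <- rps_config(k = 20, m = 2, models = c("KNN-U", "XGB"), epochs = 50,
#'                   inner_folds = 3, seed = 1)
#' fit <- rps_fit(sim$X, sim$y, cfg)
#' head(predict(fit, sim$X)$labels)
#' }
#' @export
rps_fit <- function(X, y, config = rps_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  y <- if (inherits(y, "label_vector")) y else label_vector(y)
  Xp <- as_plain_matrix(X)
  if (nrow(Xp) != length(y)) stopf("fit: X has %d rows but y has %d labels", nrow(Xp), length(y))
  if (nrow(Xp) < 2 * config$inner_folds)
    stopf("fit: need at least %d samples for %d inner folds", 2 * config$inner_folds,
          config$inner_folds)
  if (is.null(colnames(Xp))) stopf("fit: X needs gene ids as column names")
  rp_seed <- derive_seed(config$seed, 11)
  fused <- tryCatch(fuse_projections(Xp, config$k, config$m, rp_seed),
                    error = function(e) stopf("projection stage: %s", conditionMessage(e)))
  specs <- do.call(base_registry,
                   c(list(seed = derive_seed(config$seed, 12), models = config$models),
                     config$registry_args))
  preds <- tryCatch(
    oof_base_predictions(fused, y, specs, config$inner_folds,
                         derive_seed(config$seed, 13)),
    error = function(e) stopf("stacking stage: %s", conditionMessage(e)))
  composite <- build_composite(fused, preds, config$meta_mode)
  meta <- tryCatch(
    fit_meta(composite, y, hidden = config$hidden, epochs = config$epochs,
             batch_size = config$batch_size, learning_rate = config$learning_rate,
             dropout = config$dropout, seed = derive_seed(config$seed, 14)),
    error = function(e) stopf("meta-learner stage: %s", conditionMessage(e)))
  structure(list(config = config, gene_ids = colnames(Xp),
                 label_set = levels(y), positive_class = positive_class(y),
                 rp_base_seed = rp_seed, rp_k = config$k, rp_m = config$m,
                 base_models = preds$models, base_specs = specs,
                 oof_probabilities = preds$probabilities,
                 meta = meta, n_train = nrow(Xp),
                 package_version = as.character(utils::packageVersion("rpstack"))),
            class = "rpstack")
}

#' Predict subtypes with a fitted model
#'
#' Projects new samples with the archived projection seeds, queries the
#' refit-on-full-train base models, rebuilds the composite feature and
#' returns the meta-learner's argmax labels and per-class probabilities.
#' Genes are realigned to the training order by id; missing genes are an
#' error.
#'
#' @param object A fitted [rps_fit()] model.
#' @param newdata `expr_matrix` or numeric matrix with gene ids as column
#'   names.
#' @param ... Unused.
#' @return List with `labels` (a [label_vector()]) and `prob` (n x C
#'   matrix, rows summing to 1, `labels` = argmax of `prob`).
#' @export
predict.rpstack <- function(object, newdata, ...) {
  Xp <- as_plain_matrix(newdata)
  if (is.null(colnames(Xp))) stopf("predict: newdata needs gene ids as column names")
  missing <- setdiff(object$gene_ids, colnames(Xp))
  if (length(missing))
    stopf("predict: newdata lacks %d training gene(s): %s%s", length(missing),
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) ", ..." else "")
  Xp <- Xp[, object$gene_ids, drop = FALSE]
  fused <- fuse_projections(Xp, object$rp_k, object$rp_m, object$rp_base_seed)
  preds <- full_base_predictions(object$base_models, object$base_specs, fused,
                                 object$label_set)
  composite <- build_composite(fused, preds, object$config$meta_mode)
  prob <- predict_meta(object$meta, composite)
  labels <- label_vector(object$label_set[max.col(prob, ties.method = "first")],
                         label_set = object$label_set,
                         positive_class = object$positive_class)
  names(labels) <- rownames(Xp)
  list(labels = labels, prob = prob)
}

#' @export
print.rpstack <- function(x, ...) {
  cat("Random-projection stacking classifier\n")
  cat(sprintf("  trained on %d samples x %d genes\n", x$n_train, length(x$gene_ids)))
  cat(sprintf("  projections: m = %d blocks of k = %d (fused width %d)\n",
              x$rp_m, x$rp_k, x$rp_m * x$rp_k))
  cat(sprintf("  base models: %s\n", paste(names(x$base_models), collapse = ", ")))
  cat(sprintf("  meta-learner: MLP %s, meta-features = %s\n",
              paste(x$config$hidden, collapse = "-"), x$config$meta_mode))
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$label_set, collapse = ", "), x$positive_class))
  invisible(x)
}

#' @export
summary.rpstack <- function(object, ...) {
  # out-of-fold accuracy of each base model against the training labels is
  # not stored; report composite structure and meta loss trace instead
  cat("Random-projection stacking classifier\n\n")
  print(object)
  tr <- object$meta$loss_trace
  if (length(tr))
    cat(sprintf("\n  meta-learner cross-entropy: first %.4f -> final %.4f\n",
                tr[1], tr[length(tr)]))
  invisible(object)
}

#' @export
plot.rpstack <- function(x, ...) {
  tr <- x$meta$loss_trace
  if (!length(tr)) stopf("no loss trace recorded")
  plot(seq_along(tr), tr, type = "l", xlab = "checkpoint",
       ylab = "training cross-entropy", main = "meta-learner training loss", ...)
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' The archive is a single RDS file bundling the configuration, projection
#' seeds, fitted base models (boosters stored as raw bytes), meta-learner
#' weights, label set and package version; loading restores a model whose
#' predictions are bit-identical to the pre-save model.
#'
#' @param model A fitted `rpstack` model.
#' @param path File path for the archive.
#' @return `rps_save` returns `path` invisibly; `rps_load` returns the model.
#' @export
rps_save <- function(model, path) {
  stopifnot(inherits(model, "rpstack"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname rps_save
#' @export
rps_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rpstack")) stopf("'%s' is not an rpstack model archive", path)
  model
}

#' Score-ensemble baseline (one model per projection, averaged)
#'
#' The comparator strategy to feature fusion: for each of the `m` random
#' projections independently, one classifier (by default the NN base
#' learner) is trained on that single k-dimensional projection; the final
#' score is the unweighted mean of the `m` per-class probability vectors.
#'
#' @param X Training expression matrix (stage `"log"`).
#' @param y Training labels.
#' @param config An [rps_config()]; `k`, `m`, `seed` and the registry
#'   arguments are used.
#' @param newdata Samples to score (defaults to `X`).
#' @param model Name of the single base model trained per projection,
#'   default `"NN"`.
#' @return List with `prob` (n x C matrix, rows summing to 1) and `labels`.
#' @export
score_ensemble_fit_predict <- function(X, y, config = rps_config(), newdata = X,
                                       model = "NN") {
  y <- if (inherits(y, "label_vector")) y else label_vector(y)
  Xp <- as_plain_matrix(X)
  Np <- as_plain_matrix(newdata)
  Np <- Np[, colnames(Xp), drop = FALSE]
  spec <- do.call(base_registry,
                  c(list(seed = derive_seed(config$seed, 12), models = model),
                    config$registry_args))[[1]]
  d <- ncol(Xp)
  rp_seed <- derive_seed(config$seed, 11)
  acc <- NULL
  for (i in seq_len(config$m)) {
    R <- rp_matrix(d, config$k, rp_seed + i - 1L)
    fitted <- spec$fit(rp_project(Xp, R), y)
    p <- align_prob(spec$predict(fitted, rp_project(Np, R)), levels(y))
    acc <- if (is.null(acc)) p else acc + p
  }
  prob <- acc / config$m
  labels <- label_vector(levels(y)[max.col(prob, ties.method = "first")],
                         label_set = levels(y),
                         positive_class = positive_class(y))
  list(prob = prob, labels = labels)
}

#' Trainer adapters for cross-validation
#'
#' Wrap the full stacking pipeline, the score-ensemble baseline, or a
#' single base model (on fused features) as the `fit`/`predict` pair that
#' [repeated_stratified_cv()] consumes. The per-fold seed supplied by the
#' CV driver replaces the config seed so each training fold draws its own
#' projections.
#'
#' @param config An [rps_config()].
#' @return List with `fit(X, y, seed)` and `predict(model, X)`.
#' @export
rps_trainer <- function(config = rps_config()) {
  list(fit = function(X, y, seed) rps_fit(X, y, config, seed = seed),
       predict = function(model, X) predict(model, X))
}

#' @rdname rps_trainer
#' @param model Base-model name for `score_ensemble_trainer`'s per-projection
#'   learner or for `base_model_trainer`.
#' @export
score_ensemble_trainer <- function(config = rps_config(), model = "NN") {
  list(
    fit = function(X, y, seed) {
      cfg <- config
      cfg$seed <- seed
      list(X = X, y = y, cfg = cfg)
    },
    # training data is carried in the "model": each projection's learner is
    # trained lazily at prediction time against the fold's training rows
    predict = function(m, X) {
      score_ensemble_fit_predict(m$X, m$y, m$cfg, newdata = X, model = model)
    })
}

#' @rdname rps_trainer
#' @export
base_model_trainer <- function(config = rps_config(), model = "XGB") {
  list(fit = function(X, y, seed) {
    spec <- do.call(base_registry,
                    c(list(seed = derive_seed(seed, 12), models = model),
                      config$registry_args))[[1]]
    fused <- fuse_projections(X, config$k, config$m, derive_seed(seed, 11))
    list(fit = spec$fit(fused, y), spec = spec, y = y,
         k = config$k, m = config$m, rp_seed = derive_seed(seed, 11),
         genes = colnames(X))
  },
  predict = function(m, X) {
    fused <- fuse_projections(X[, m$genes, drop = FALSE], m$k, m$m, m$rp_seed)
    prob <- align_prob(m$spec$predict(m$fit, fused), levels(m$y))
    labels <- label_vector(levels(m$y)[max.col(prob, ties.method = "first")],
                           label_set = levels(m$y),
                           positive_class = positive_class(m$y))
    list(prob = prob, labels = labels)
  })
}
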