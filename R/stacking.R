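# Stacked generalization: leakage-safe construction of meta-learner inputs.

#' Out-of-fold base-model predictions
#'
#' Produces the meta-training inputs of the stacked classifier. The samples
#' are split into `inner_folds` stratified folds; every sample's base-model
#' prediction comes from models that never saw it during training. Each spec
#' is then refit on all rows for inference-time use.
#'
#' @param features Numeric matrix (typically [fuse_projections()] output).
#' @param labels A [label_vector()] (or factor) of length `nrow(features)`.
#' @param specs List of [rps_model_spec()] objects.
#' @param inner_folds Number of stratified inner folds, `>= 2`.
#' @param seed Integer seed for the fold split.
#' @return An object of class `rps_base_predictions`: list with
#'   `probabilities` (list per model of n x C matrices), `hard_labels`
#'   (n x N character matrix, argmax of the probabilities), `models`
#'   (refit-on-all-rows fitted models, for prediction), `provenance =
#'   "out_of_fold"`, `label_set` and the fold assignment.
#' @export
oof_base_predictions <- function(features, labels, specs, inner_folds = 5, seed = 1L) {
  y <- if (inherits(labels, "label_vector")) labels else label_vector(labels)
  n <- nrow(features)
  if (length(y) != n) stopf("labels length (%d) != feature rows (%d)", length(y), n)
  if (inner_folds < 2) stopf("inner_folds must be >= 2")
  counts <- table(y)
  if (length(counts) < 2 || any(counts == 0))
    stopf("stratification impossible: need at least two represented classes")
  if (min(counts) < inner_folds)
    stopf("class '%s' has %d member(s), fewer than inner_folds = %d; reduce the fold count",
          names(counts)[which.min(counts)], min(counts), inner_folds)
  fold <- stratified_folds(y, inner_folds, seed)
  lv <- levels(y)
  N <- length(specs)
  probs <- lapply(seq_len(N), function(i)
    matrix(NA_real_, n, length(lv), dimnames = list(rownames(features), lv)))
  names(probs) <- vapply(specs, `[[`, "", "name")
  for (f in seq_len(inner_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    for (i in seq_len(N)) {
      m <- specs[[i]]$fit(features[tr, , drop = FALSE], subset_labels(y, tr))
      p <- specs[[i]]$predict(m, features[te, , drop = FALSE])
      probs[[i]][te, ] <- align_prob(p, lv)
    }
  }
  full <- lapply(specs, function(s) s$fit(features, y))
  names(full) <- names(probs)
  hard <- vapply(probs, function(p) lv[max.col(p, ties.method = "first")],
                 character(n))
  if (is.null(dim(hard))) hard <- matrix(hard, nrow = n)
  dimnames(hard) <- list(rownames(features), names(probs))
  structure(list(probabilities = probs, hard_labels = hard, models = full,
                 provenance = "out_of_fold", label_set = lv, folds = fold),
            class = "rps_base_predictions")
}

# Reorder / complete a probability matrix to the full level set.
align_prob <- function(p, lv) {
  out <- matrix(0, nrow(p), length(lv), dimnames = list(rownames(p), lv))
  hit <- intersect(colnames(p), lv)
  out[, hit] <- p[, hit, drop = FALSE]
  out
}

# Base predictions from already-fitted full models (inference path).
full_base_predictions <- function(models, specs, features, lv) {
  N <- length(specs)
  probs <- vector("list", N)
  for (i in seq_len(N)) {
    probs[[i]] <- align_prob(specs[[i]]$predict(models[[i]], features), lv)
  }
  names(probs) <- vapply(specs, `[[`, "", "name")
  hard <- vapply(probs, function(p) lv[max.col(p, ties.method = "first")],
                 character(nrow(features)))
  if (is.null(dim(hard))) hard <- matrix(hard, nrow = nrow(features))
  dimnames(hard) <- list(rownames(features), names(probs))
  structure(list(probabilities = probs, hard_labels = hard, models = models,
                 provenance = "refit_full", label_set = lv, folds = NULL),
            class = "rps_base_predictions")
}

#' Build the composite feature matrix for the meta-learner
#'
#' Concatenates the fused random-projection features with the base-model
#' predictions: in `"hard_labels"` mode each binary model contributes one
#' 0/1 column (multiclass models one one-hot block); in `"probabilities"`
#' mode each model contributes its C per-class probability columns.
#'
#' @param fused Numeric matrix of fused features (n x m*k).
#' @param preds An `rps_base_predictions` object with matching rows.
#' @param mode `"hard_labels"` or `"probabilities"`.
#' @return Numeric matrix n x (m*k + meta_width); the first m*k columns are
#'   the fused features unchanged.
#' @export
build_composite <- function(fused, preds, mode = c("hard_labels", "probabilities")) {
  mode <- match.arg(mode)
  if (length(preds$probabilities) == 0) return(as_plain_matrix(fused))
  n <- nrow(fused)
  if (nrow(preds$hard_labels) != n)
    stopf("row mismatch: fused has %d rows, predictions %d", n, nrow(preds$hard_labels))
  lv <- preds$label_set
  if (mode == "probabilities") {
    meta <- do.call(cbind, lapply(names(preds$probabilities), function(nm) {
      p <- preds$probabilities[[nm]]
      colnames(p) <- paste0(nm, ".", lv)
      p
    }))
  } else if (length(lv) == 2) {
    meta <- matrix(as.integer(preds$hard_labels == lv[2]), n,
                   ncol(preds$hard_labels))
    colnames(meta) <- colnames(preds$hard_labels)
  } else {
    meta <- do.call(cbind, lapply(seq_len(ncol(preds$hard_labels)), function(j) {
      oh <- matrix(0L, n, length(lv),
                   dimnames = list(NULL, paste0(colnames(preds$hard_labels)[j], ".", lv)))
      oh[cbind(seq_len(n), match(preds$hard_labels[, j], lv))] <- 1L
      oh
    }))
  }
  cbind(as_plain_matrix(fused), meta)
}

#' Fit the MLP meta-learner on composite features
#'
#' Trains the four-hidden-layer network (128-64-32-16 units, ReLU, dropout
#' 0.2) with softmax cross-entropy, an Adam optimizer at learning rate 1e-4
#' and class-weighted random batch sampling, for a fixed epoch budget.
#'
#' @param composite Numeric matrix from [build_composite()].
#' @param labels A [label_vector()] or factor.
#' @param hidden Hidden-layer widths, default `c(128, 64, 32, 16)`.
#' @param epochs Training epochs, default 1000.
#' @param batch_size Batch size, default 64.
#' @param learning_rate Adam step size, default 1e-4.
#' @param dropout Dropout rate after each hidden layer, default 0.2.
#' @param seed Integer seed (initialization, dropout masks, sampling).
#' @return An `rps_mlp` model; use [predict_meta()] for probabilities.
#' @export
fit_meta <- function(composite, labels, hidden = c(128, 64, 32, 16),
                     epochs = 1000, batch_size = 64, learning_rate = 1e-4,
                     dropout = 0.2, seed = 1L) {
  y <- if (inherits(labels, "label_vector")) labels else label_vector(labels)
  if (nrow(composite) != length(y))
    stopf("composite rows (%d) != labels (%d)", nrow(composite), length(y))
  if (any(!is.finite(composite))) stopf("non-finite values in composite features")
  mlp_fit(composite, y, hidden = hidden, epochs = epochs, batch_size = batch_size,
          lr = learning_rate, dropout = dropout, seed = seed)
}

#' Predict per-class probabilities from a fitted meta-learner
#'
#' @param meta An `rps_mlp` model from [fit_meta()].
#' @param composite Composite feature matrix with the training width.
#' @return n x C probability matrix (rows sum to 1).
#' @export
predict_meta <- function(meta, composite) {
  mlp_predict(meta, composite)
}
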