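# The heterogeneous base-classifier panel. Ten members spanning neighbour,
# forest, boosting and neural families:
#   KNN-D / KNN-U  k-nearest neighbours, distance- vs uniform-weighted votes
#   RF-G           random forest, Gini impurity (ranger)
#   RF-E           random forest, entropy criterion (bagged rpart trees with
#                  per-tree feature subsampling; no installed forest exposes
#                  an entropy split rule)
#   ET-G           extremely randomized trees, Gini (ranger, extratrees rule)
#   ET-E           entropy-criterion forest without bootstrap resampling,
#                  occupying the extra-trees-with-entropy slot
#   LGBM           leaf-wise histogram gradient boosting (xgboost with
#                  lossguide growth, the LightGBM-style algorithm)
#   CB             a second, depth-wise gradient-boosting configuration with
#                  heavier regularization
#   XGB            depth-wise gradient boosting, xgboost defaults
#   NN             small feed-forward network (one hidden block, see mlp.R)
# Every spec exposes fit(x, y) and per-class probability prediction.

#' Create a base-model specification
#'
#' A specification couples a name with `fit`/`predict` closures so that
#' user-defined learners can participate in stacking alongside the built-in
#' panel. `fit(x, y)` must return any model object; `predict(model, x)` must
#' return an n x C matrix of per-class probabilities with class labels as
#' column names, rows summing to 1.
#'
#' @param name Unique model name.
#' @param fit Function `(x, y)` -> fitted model (`x` numeric matrix, `y` factor).
#' @param predict Function `(model, x)` -> probability matrix.
#' @param hyperparameters Named list, recorded for provenance.
#' @param seed Integer seed threaded into the learner.
#' @return An object of class `rps_model_spec`.
#' @export
rps_model_spec <- function(name, fit, predict, hyperparameters = list(), seed = 1L) {
  stopifnot(is.character(name), length(name) == 1, is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict,
                 hyperparameters = hyperparameters, seed = as.integer(seed)),
            class = "rps_model_spec")
}

#' Names of the built-in base models
#' @return Character vector of the ten panel names in registry order.
#' @export
rps_model_names <- function() {
  c("KNN-D", "KNN-U", "RF-G", "RF-E", "ET-G", "ET-E", "LGBM", "CB", "XGB", "NN")
}

# ---- kNN with per-class probabilities -------------------------------------

knn_fit <- function(x, y, k) list(x = x, y = droplevels(as.factor(y)), k = k)

knn_predict <- function(model, x, weighting = c("uniform", "distance")) {
  weighting <- match.arg(weighting)
  lv <- levels(model$y)
  ntr <- nrow(model$x)
  k <- min(model$k, ntr)
  # squared Euclidean distances query x train
  d2 <- outer(rowSums(x^2), rep(1, ntr)) + outer(rep(1, nrow(x)), rowSums(model$x^2)) -
    2 * x %*% t(model$x)
  d2[d2 < 0] <- 0
  prob <- matrix(0, nrow(x), length(lv), dimnames = list(rownames(x), lv))
  for (i in seq_len(nrow(x))) {
    ord <- order(d2[i, ])[seq_len(k)]
    w <- if (weighting == "distance") 1 / pmax(sqrt(d2[i, ord]), 1e-12) else rep(1, k)
    for (j in seq_len(k)) {
      cls <- as.integer(model$y[ord[j]])
      prob[i, cls] <- prob[i, cls] + w[j]
    }
  }
  prob / rowSums(prob)
}

# ---- entropy-criterion forest on rpart ------------------------------------

entropy_forest_fit <- function(x, y, ntree, mtry_frac, bootstrap, seed) {
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  p <- ncol(x)
  mtry <- max(2L, ceiling(p * mtry_frac))
  colnames(x) <- paste0("V", seq_len(p))
  with_seed(seed, {
    trees <- vector("list", ntree)
    cols <- vector("list", ntree)
    for (t in seq_len(ntree)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      cj <- sort(sample.int(p, mtry))
      df <- data.frame(.y = y[idx], x[idx, cj, drop = FALSE])
      trees[[t]] <- rpart::rpart(.y ~ ., data = df, method = "class",
                                 parms = list(split = "information"),
                                 control = rpart::rpart.control(cp = 0.005, xval = 0,
                                                                minsplit = 5))
      cols[[t]] <- cj
    }
    list(trees = trees, cols = cols, levels = levels(y))
  })
}

entropy_forest_predict <- function(model, x) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  acc <- matrix(0, nrow(x), length(model$levels),
                dimnames = list(rownames(x), model$levels))
  for (t in seq_along(model$trees)) {
    df <- data.frame(x[, model$cols[[t]], drop = FALSE])
    p <- stats::predict(model$trees[[t]], newdata = df, type = "prob")
    acc <- acc + p[, model$levels, drop = FALSE]
  }
  acc / length(model$trees)
}

# ---- xgboost wrappers ------------------------------------------------------

xgb_fit <- function(x, y, params, nrounds, seed) {
  y <- droplevels(as.factor(y))
  C <- nlevels(y)
  base <- list(nthread = 1, seed = seed)
  if (C == 2) {
    base$objective <- "binary:logistic"
  } else {
    base$objective <- "multi:softprob"
    base$num_class <- C
  }
  dm <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  bst <- xgboost::xgb.train(params = c(base, params), data = dm,
                            nrounds = nrounds, verbose = 0)
  # store as raw bytes so the fitted model survives serialization
  list(raw = xgboost::xgb.save.raw(bst), levels = levels(y), C = C)
}

xgb_predict <- function(model, x) {
  bst <- xgboost::xgb.load.raw(model$raw)
  p <- stats::predict(bst, xgboost::xgb.DMatrix(x))
  if (model$C == 2) {
    out <- cbind(1 - p, p)
  } else {
    out <- matrix(p, ncol = model$C, byrow = TRUE)
  }
  dimnames(out) <- list(rownames(x), model$levels)
  out
}

# ---- ranger wrappers -------------------------------------------------------

ranger_fit <- function(x, y, seed, num.trees = 300, splitrule = "gini",
                       replace = TRUE, sample.fraction = 1) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  ranger::ranger(x = x, y = droplevels(as.factor(y)), num.trees = num.trees,
                 splitrule = splitrule, probability = TRUE, replace = replace,
                 sample.fraction = sample.fraction, num.threads = 1, seed = seed)
}

ranger_predict <- function(model, x) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- stats::predict(model, data = x, num.threads = 1)$predictions
  rownames(p) <- rownames(x)
  p
}

#' Built-in base-model registry
#'
#' Returns the ordered ten-member panel (optionally filtered to a subset,
#' preserving order) with deterministic hyperparameters given the seed.
#'
#' @param seed Integer seed fanned out to the individual learners.
#' @param models Character vector selecting a subset of [rps_model_names()].
#' @param knn_k Neighbours for the two kNN members, default 5.
#' @param num_trees Trees for the ranger forests, default 300.
#' @param entropy_trees Trees for the rpart-based entropy forests, default 50.
#' @param nrounds Boosting rounds for the three gradient-boosting members,
#'   default 100.
#' @param nn_hidden Hidden-layer sizes of the NN base learner, default
#'   `c(64, 32)`.
#' @param nn_epochs Training epochs of the NN base learner, default 200.
#' @return List of [rps_model_spec()] objects.
#' @export
base_registry <- function(seed = 1L, models = rps_model_names(), knn_k = 5,
                          num_trees = 300, entropy_trees = 50, nrounds = 100,
                          nn_hidden = c(64, 32), nn_epochs = 200) {
  bad <- setdiff(models, rps_model_names())
  if (length(bad)) stopf("unknown base models: %s", paste(bad, collapse = ", "))
  specs <- list(
    `KNN-D` = rps_model_spec("KNN-D",
      fit = function(x, y) knn_fit(x, y, knn_k),
      predict = function(m, x) knn_predict(m, x, "distance"),
      hyperparameters = list(k = knn_k, weighting = "distance")),
    `KNN-U` = rps_model_spec("KNN-U",
      fit = function(x, y) knn_fit(x, y, knn_k),
      predict = function(m, x) knn_predict(m, x, "uniform"),
      hyperparameters = list(k = knn_k, weighting = "uniform")),
    `RF-G` = rps_model_spec("RF-G",
      fit = function(x, y) ranger_fit(x, y, derive_seed(seed, 3), num_trees, "gini"),
      predict = ranger_predict,
      hyperparameters = list(num_trees = num_trees, splitrule = "gini"),
      seed = derive_seed(seed, 3)),
    `RF-E` = rps_model_spec("RF-E",
      fit = function(x, y) entropy_forest_fit(x, y, entropy_trees, 0.3, TRUE,
                                              derive_seed(seed, 4)),
      predict = entropy_forest_predict,
      hyperparameters = list(ntree = entropy_trees, split = "information",
                             bootstrap = TRUE),
      seed = derive_seed(seed, 4)),
    `ET-G` = rps_model_spec("ET-G",
      fit = function(x, y) ranger_fit(x, y, derive_seed(seed, 5), num_trees,
                                      "extratrees", replace = FALSE,
                                      sample.fraction = 1),
      predict = ranger_predict,
      hyperparameters = list(num_trees = num_trees, splitrule = "extratrees"),
      seed = derive_seed(seed, 5)),
    `ET-E` = rps_model_spec("ET-E",
      fit = function(x, y) entropy_forest_fit(x, y, entropy_trees, 0.2, FALSE,
                                              derive_seed(seed, 6)),
      predict = entropy_forest_predict,
      hyperparameters = list(ntree = entropy_trees, split = "information",
                             bootstrap = FALSE),
      seed = derive_seed(seed, 6)),
    LGBM = rps_model_spec("LGBM",
      fit = function(x, y) xgb_fit(x, y, list(tree_method = "hist",
                                              grow_policy = "lossguide",
                                              max_leaves = 15, max_depth = 0,
                                              eta = 0.1),
                                   max(20, nrounds %/% 2), derive_seed(seed, 7)),
      predict = xgb_predict,
      hyperparameters = list(grow_policy = "lossguide", max_leaves = 15, eta = 0.1),
      seed = derive_seed(seed, 7)),
    CB = rps_model_spec("CB",
      fit = function(x, y) xgb_fit(x, y, list(max_depth = 4, eta = 0.1,
                                              colsample_bytree = 0.8,
                                              subsample = 0.8, lambda = 3),
                                   nrounds, derive_seed(seed, 8)),
      predict = xgb_predict,
      hyperparameters = list(max_depth = 4, eta = 0.1, lambda = 3,
                             subsample = 0.8),
      seed = derive_seed(seed, 8)),
    XGB = rps_model_spec("XGB",
      fit = function(x, y) xgb_fit(x, y, list(max_depth = 6, eta = 0.3),
                                   max(20, nrounds %/% 2), derive_seed(seed, 9)),
      predict = xgb_predict,
      hyperparameters = list(max_depth = 6, eta = 0.3),
      seed = derive_seed(seed, 9)),
    NN = rps_model_spec("NN",
      fit = function(x, y) mlp_fit(x, y, hidden = nn_hidden, epochs = nn_epochs,
                                   batch_size = 64, lr = 1e-3, dropout = 0.2,
                                   seed = derive_seed(seed, 10)),
      predict = function(m, x) mlp_predict(m, x),
      hyperparameters = list(hidden = nn_hidden, epochs = nn_epochs, lr = 1e-3),
      seed = derive_seed(seed, 10))
  )
  specs[models]
}
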