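# Metrics, repeated stratified cross-validation, paired comparison.

# Stratified fold assignment: within each class, members are shuffled
# (seeded) and dealt round-robin, so per-fold class proportions deviate from
# the global ones by at most one sample.
stratified_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  n <- length(y)
  if (any(table(y) < folds))
    stopf("stratification impossible: smallest class has %d member(s) for %d folds",
          min(table(y)), folds)
  assignment <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      # rotate the fold cycle between classes so fold sizes stay balanced
      assignment[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  assignment
}

#' Classification metrics for one evaluation fold
#'
#' Computes accuracy, F1, Matthews correlation coefficient and AUC.
#' F1 is reported for the designated positive class (`average = "binary"`,
#' the default) or macro-averaged over classes. MCC is computed from the
#' confusion matrix, with the zero-marginal convention MCC = 0. AUC is the
#' Mann-Whitney probability that a random positive-class sample outscores a
#' random negative one, ties counted 1/2; it needs `y_score` and a binary
#' truth, and is returned as `NA` (with a warning) when `y_true` holds a
#' single class.
#'
#' @param y_true A [label_vector()] (or factor) of reference labels.
#' @param y_pred Predicted labels.
#' @param y_score Optional numeric scores for the positive class (for AUC).
#' @param positive Positive class; defaults to the `positive_class` of
#'   `y_true`.
#' @param average `"binary"` or `"macro"` for F1.
#' @return Named list with `accuracy`, `f1`, `mcc`, `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL, positive = NULL,
                            average = c("binary", "macro")) {
  average <- match.arg(average)
  yt <- if (inherits(y_true, "label_vector")) y_true else label_vector(y_true)
  lv <- levels(yt)
  yp <- factor(as.character(y_pred), levels = lv)
  if (length(yt) != length(yp))
    stopf("length mismatch: %d true vs %d predicted", length(yt), length(yp))
  if (any(is.na(yp))) stopf("predicted labels outside the label set")
  pos <- positive %||% positive_class(yt)
  acc <- mean(yp == yt)

  f1_one <- function(cls) {
    tp <- sum(yp == cls & yt == cls)
    fp <- sum(yp == cls & yt != cls)
    fn <- sum(yp != cls & yt == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  f1 <- if (average == "binary") f1_one(pos) else mean(vapply(lv, f1_one, 0))

  mcc <- mcc_from_table(table(factor(yt, lv), factor(yp, lv)))

  auc <- NA_real_
  if (!is.null(y_score)) {
    if (length(y_score) != length(yt)) stopf("y_score length mismatch")
    is_pos <- yt == pos
    if (all(is_pos) || !any(is_pos)) {
      warnf("AUC undefined: y_true contains a single class")
    } else {
      r <- rank(y_score)  # average ranks handle ties as 1/2
      n1 <- sum(is_pos)
      n0 <- sum(!is_pos)
      auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(accuracy = acc, f1 = f1, mcc = mcc, auc = auc)
}

# Multiclass MCC from a confusion matrix (reduces to the familiar 2x2
# closed form for binary labels); any zero marginal gives 0.
mcc_from_table <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  correct <- sum(diag(tab))
  truth_marg <- rowSums(tab)
  pred_marg <- colSums(tab)
  num <- correct * n - sum(truth_marg * pred_marg)
  den <- sqrt(n^2 - sum(pred_marg^2)) * sqrt(n^2 - sum(truth_marg^2))
  if (den == 0) return(0)
  num / den
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat an independent stratified partition is drawn (seeded by
#' `seed + repeat`); the trainer is fitted on the k-1 training folds and
#' scored on the held-out fold. All training-side randomness (random
#' projections, model seeds) lives inside the trainer, so no information
#' leaks from the test fold.
#'
#' @param X Numeric matrix or `expr_matrix` (samples x features).
#' @param y A [label_vector()] (or factor).
#' @param trainer List with `fit(X, y, seed)` returning a model and
#'   `predict(model, X)` returning `list(labels =, prob =)` where `prob` has
#'   one column per class. See [rps_trainer()].
#' @param repeats Number of repeats, default 10.
#' @param folds Folds per repeat, default 5.
#' @param seed Integer seed.
#' @param average F1 averaging, passed to [compute_metrics()].
#' @return An object of class `rps_cv`: list with `metrics` (data.frame of
#'   repeats x folds rows: `rep`, `fold`, `accuracy`, `f1`, `mcc`, `auc`),
#'   `folds` (list of per-repeat assignment vectors), `seed`.
#' @export
repeated_stratified_cv <- function(X, y, trainer, repeats = 10, folds = 5,
                                   seed = 1L, average = "binary") {
  y <- if (inherits(y, "label_vector")) y else label_vector(y)
  pos <- positive_class(y)
  Xp <- as_plain_matrix(X)
  rows <- list()
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, derive_seed(seed, 100 + r))
    assignments[[r]] <- fold
    for (f in seq_len(folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      model <- trainer$fit(Xp[tr, , drop = FALSE], subset_labels(y, tr),
                           derive_seed(seed, 1000 * r + f))
      pred <- trainer$predict(model, Xp[te, , drop = FALSE])
      score <- if (!is.null(pred$prob)) pred$prob[, pos] else NULL
      m <- compute_metrics(subset_labels(y, te), pred$labels, score,
                           positive = pos, average = average)
      rows[[length(rows) + 1]] <- data.frame(rep = r, fold = f,
                                             accuracy = m$accuracy, f1 = m$f1,
                                             mcc = m$mcc, auc = m$auc)
    }
  }
  structure(list(metrics = do.call(rbind, rows), folds = assignments,
                 seed = as.integer(seed), repeats = repeats, n_folds = folds),
            class = "rps_cv")
}

#' @export
print.rps_cv <- function(x, ...) {
  cat(sprintf("stratified cross-validation: %d repeat(s) x %d fold(s)\n",
              x$repeats, x$n_folds))
  for (m in c("accuracy", "f1", "mcc", "auc")) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-8s mean %.4f  sd %.4f\n", m, mean(v, na.rm = TRUE),
                stats::sd(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.rps_cv <- function(object, ...) {
  mets <- c("accuracy", "f1", "mcc", "auc")
  data.frame(metric = mets,
             mean = vapply(mets, function(m) mean(object$metrics[[m]], na.rm = TRUE), 0),
             sd = vapply(mets, function(m) stats::sd(object$metrics[[m]], na.rm = TRUE), 0),
             row.names = NULL)
}

#' Paired comparison of two cross-validation results
#'
#' Compares one metric between two `rps_cv` runs that share identical fold
#' assignments (same seed and partition), using a two-sided Wilcoxon
#' signed-rank test on the paired per-fold differences (exact sign-flip
#' enumeration for up to 14 non-zero pairs, which handles tied ranks; a
#' tie-corrected normal approximation beyond). Zero differences are dropped;
#' if all differences are zero the p-value is reported as 1. A paired
#' t-test is available via `method = "t"`.
#'
#' @param a,b `rps_cv` objects with identical fold structure.
#' @param metric One of `"accuracy"`, `"f1"`, `"mcc"`, `"auc"`.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return List with `p_value`, `median_diff` (median of a - b), and
#'   `direction` (`"a"`, `"b"` or `"none"`).
#' @export
paired_comparison <- function(a, b, metric = "accuracy",
                              method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (!identical(a$folds, b$folds))
    stopf("fold assignments differ; comparisons must be paired on the same partitions")
  va <- a$metrics[[metric]]
  vb <- b$metrics[[metric]]
  if (is.null(va) || is.null(vb)) stopf("unknown metric '%s'", metric)
  d <- va - vb
  d <- d[is.finite(d)]
  med <- stats::median(d)
  direction <- if (med > 0) "a" else if (med < 0) "b" else "none"
  if (method == "t") {
    p <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else stats::t.test(d)$p.value
  } else {
    p <- signed_rank_test(d)
  }
  list(p_value = p, median_diff = med, direction = direction)
}

# Two-sided Wilcoxon signed-rank p-value. Zeros dropped; average ranks for
# ties. Exact by enumeration of all sign assignments when <= 14 non-zero
# pairs remain, else normal approximation with Var(W) = sum(rank^2).
signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r * sign(d))
  if (n <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    Wnull <- as.vector(signs %*% r)
    return(mean(abs(Wnull) >= abs(W) - 1e-9))
  }
  z <- W / sqrt(sum(r^2))
  2 * stats::pnorm(-abs(z))
}
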