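# Brute-force oracles and small fixtures shared across tests. Everything is
# generated in code; no data files.

# Direct-counting metrics oracle: confusion-table arithmetic plus all-pairs
# AUC with explicit 1/2 tie handling. Deliberately naive (O(n^2) AUC).
oracle_metrics <- function(y_true, y_pred, y_score, pos) {
  acc <- mean(y_pred == y_true)
  tp <- sum(y_pred == pos & y_true == pos)
  fp <- sum(y_pred == pos & y_true != pos)
  fn <- sum(y_pred != pos & y_true == pos)
  tn <- sum(y_pred != pos & y_true != pos)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  pos_scores <- y_score[y_true == pos]
  neg_scores <- y_score[y_true != pos]
  auc <- NA_real_
  if (length(pos_scores) && length(neg_scores)) {
    wins <- 0
    for (p in pos_scores) for (q in neg_scores)
      wins <- wins + (p > q) + 0.5 * (p == q)
    auc <- wins / (length(pos_scores) * length(neg_scores))
  }
  list(accuracy = acc, f1 = f1, mcc = mcc, auc = auc)
}

# Pathological base learner for the leakage test: if a test sample was seen
# during training it predicts that sample's own training label with
# certainty, otherwise it always predicts the first class. Out-of-fold
# stacking must therefore yield all-first-class predictions, while fitting
# on all rows and predicting the same rows reproduces y exactly.
memorizing_spec <- function() {
  rps_model_spec(
    name = "MEMO",
    fit = function(x, y) list(keys = apply(x, 1, paste, collapse = "\r"),
                              y = y, levels = levels(y)),
    predict = function(m, x) {
      keys <- apply(x, 1, paste, collapse = "\r")
      prob <- matrix(0, nrow(x), length(m$levels),
                     dimnames = list(NULL, m$levels))
      hit <- match(keys, m$keys)
      for (i in seq_len(nrow(x))) {
        cls <- if (is.na(hit[i])) 1L else as.integer(m$y[hit[i]])
        prob[i, cls] <- 1
      }
      prob
    })
}

# Two well-separated Gaussian blobs (for meta-learner sanity checks).
make_blobs <- function(n = 200, p = 10, separation = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "B", 1] <- x[y == "B", 1] + separation
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = label_vector(y))
}

# Reduced-size pipeline configuration used by the heavier experiments; the
# method parameters (architecture, optimizer, sampling) stay the reference
# ones, only problem sizes and iteration budgets shrink.
scaled_config <- function(k, m, seed, inner_folds = 3) {
  rps_config(k = k, m = m, inner_folds = inner_folds, epochs = 300, seed = seed,
             num_trees = 150, entropy_trees = 30, nrounds = 60, nn_epochs = 100)
}

# Tiny labeled dataset for smoke tests.
tiny_dataset <- function(n = 60, d = 120, delta = 2.5, seed = 42) {
  synth_generate(synth_config(n_samples = n, n_genes = d, n_signal_genes = 20,
                              effect_size_delta = delta, n_coexpression_blocks = 4,
                              seed = seed))
}
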