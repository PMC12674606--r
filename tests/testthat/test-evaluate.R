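test_that("metrics hit their closed-form values on worked confusion matrices", {
  y <- label_vector(rep(c("neg", "pos"), each = 4), positive_class = "pos")
  perfect <- compute_metrics(y, as.character(y), y_score = c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(perfect, list(accuracy = 1, f1 = 1, mcc = 1, auc = 1))

  # all predictions one class on mixed truth: zero-marginal convention MCC = 0
  mono <- compute_metrics(y, rep("neg", 8))
  expect_identical(mono$mcc, 0)

  # TP=40 FN=10 FP=5 TN=45
  yt <- label_vector(c(rep("pos", 50), rep("neg", 50)), positive_class = "pos")
  yp <- c(rep("pos", 40), rep("neg", 10), rep("pos", 5), rep("neg", 45))
  m <- compute_metrics(yt, yp)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 80 / 95)
  expect_equal(m$mcc, (40 * 45 - 5 * 10) / sqrt(45 * 55 * 50 * 50))

  expect_error(compute_metrics(yt, yp[1:10]), "length mismatch")
  one_class <- label_vector(rep("pos", 4), label_set = c("neg", "pos"))
  expect_warning(u <- compute_metrics(one_class, rep("pos", 4), y_score = 1:4),
                 "single class")
  expect_true(is.na(u$auc))
})

test_that("metrics agree with a brute-force counting oracle on random cases", {
  set.seed(17)
  for (case in 1:300) {
    n <- sample(4:30, 1)
    yt <- c("n", "p", sample(c("n", "p"), n - 2, replace = TRUE))
    yp <- sample(c("n", "p"), n, replace = TRUE)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # coarse grid forces ties
    got <- compute_metrics(label_vector(yt, positive_class = "p"), yp, sc)
    want <- oracle_metrics(yt, yp, sc, "p")
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone score transforms and MCC to class swaps", {
  set.seed(8)
  yt <- label_vector(sample(c("n", "p"), 40, replace = TRUE, prob = c(0.6, 0.4)),
                     positive_class = "p")
  sc <- rnorm(40)
  yp <- sample(c("n", "p"), 40, replace = TRUE)
  base <- compute_metrics(yt, yp, sc)
  expect_equal(compute_metrics(yt, yp, exp(3 * sc) + 2)$auc, base$auc)

  swap <- c(n = "p", p = "n")
  swapped <- compute_metrics(label_vector(swap[as.character(yt)], positive_class = "p"),
                             swap[yp])
  expect_equal(swapped$mcc, base$mcc)
})

test_that("repeated stratified CV partitions samples and tracks a dummy's accuracy", {
  sim <- tiny_dataset(n = 55, d = 30)
  majority <- names(which.max(table(sim$y)))
  dummy <- list(fit = function(X, y, seed) majority,
                predict = function(model, X)
                  list(labels = rep(model, nrow(X)), prob = NULL))
  res <- repeated_stratified_cv(sim$X, sim$y, dummy, repeats = 10, folds = 5, seed = 3)
  expect_identical(nrow(res$metrics), 50L)

  for (r in c(1, 7)) {
    fold <- res$folds[[r]]
    expect_setequal(fold, 1:5)
    expect_identical(length(fold), 55L)
    # stratification: per-fold class proportions within one sample of global
    for (f in 1:5) {
      tab <- table(sim$y[fold == f])
      expected <- table(sim$y) / 5
      expect_true(all(abs(tab - expected) <= 1))
    }
  }
  expect_equal(mean(res$metrics$accuracy), mean(sim$y == majority), tolerance = 0.06)
})

test_that("paired comparison matches exact enumeration and reference implementations", {
  base <- list(metrics = data.frame(accuracy = rep(0.9, 6)), folds = list(1:10))
  same <- paired_comparison(structure(base, class = "rps_cv"),
                            structure(base, class = "rps_cv"))
  expect_identical(same$p_value, 1)
  expect_identical(same$direction, "none")

  # differences (+1,+1,+1,+1,+1,-1)*0.01: all |d| tie at rank 3.5, so the
  # exact two-sided p is Pr(|3.5*(n+ - n-)| >= 14) over the 2^6 sign flips
  d <- c(1, 1, 1, 1, 1, -1) * 0.01
  a <- structure(list(metrics = data.frame(accuracy = 0.8 + d), folds = list(1:6)),
                 class = "rps_cv")
  b <- structure(list(metrics = data.frame(accuracy = rep(0.8, 6)), folds = list(1:6)),
                 class = "rps_cv")
  got <- paired_comparison(a, b)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  wnull <- abs(signs %*% rep(3.5, 6))
  expect_equal(got$p_value, mean(wnull >= 14))
  expect_identical(got$direction, "a")

  # tie-free case agrees with stats::wilcox.test's exact test
  set.seed(21)
  da <- data.frame(accuracy = runif(12))
  db <- data.frame(accuracy = da$accuracy + rnorm(12, sd = 0.05))
  A <- structure(list(metrics = da, folds = list(1:12)), class = "rps_cv")
  B <- structure(list(metrics = db, folds = list(1:12)), class = "rps_cv")
  ref <- wilcox.test(da$accuracy, db$accuracy, paired = TRUE, exact = TRUE)
  expect_equal(paired_comparison(A, B)$p_value, ref$p.value)

  # constant shift on 50 folds is overwhelmingly significant, favoring b
  a50 <- structure(list(metrics = data.frame(accuracy = runif(50, 0.7, 0.9)),
                        folds = list(1:50)), class = "rps_cv")
  b50 <- structure(list(metrics = data.frame(accuracy = a50$metrics$accuracy + 0.02),
                        folds = list(1:50)), class = "rps_cv")
  shift <- paired_comparison(a50, b50)
  expect_lt(shift$p_value, 0.01)
  expect_identical(shift$direction, "b")
  expect_lt(paired_comparison(a50, b50, method = "t")$p_value, 0.01)

  mismatch <- structure(list(metrics = da, folds = list(c(2:12, 1))), class = "rps_cv")
  expect_error(paired_comparison(A, mismatch), "fold assignments differ")
})
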