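test_that("the built-in registry exposes ten named members that all fit a toy task", {
  specs <- base_registry(seed = 1)
  expect_identical(vapply(specs, `[[`, "", "name"),
                   setNames(rps_model_names(), rps_model_names()))

  top3 <- base_registry(seed = 1, models = c("RF-G", "CB", "NN"))
  expect_identical(names(top3), c("RF-G", "CB", "NN"))
  expect_error(base_registry(models = "SVM"), "unknown base models")

  # smoke contract: every member fits 40 samples and returns simplex rows
  sim <- tiny_dataset(n = 40, d = 25)
  x <- unclass(sim$X)[, 1:12]
  y <- sim$y
  fast <- base_registry(seed = 2, num_trees = 30, entropy_trees = 8, nrounds = 10,
                        nn_epochs = 20)
  for (s in fast) {
    fit <- s$fit(x, y)
    p <- s$predict(fit, x)
    expect_identical(dim(p), c(40L, 2L))
    expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6,
                 ignore_attr = TRUE, label = s$name)
    expect_true(all(colnames(p) %in% levels(y)), label = s$name)
  }
})

test_that("out-of-fold stacking blocks label leakage that refit-on-all would commit", {
  sim <- tiny_dataset(n = 48, d = 20)
  x <- unclass(sim$X)
  y <- sim$y
  memo <- list(memorizing_spec())

  oof <- oof_base_predictions(x, y, memo, inner_folds = 4, seed = 9)
  expect_identical(oof$provenance, "out_of_fold")
  # the memorizer never saw the held-out rows: it falls back to class 1
  expect_true(all(oof$hard_labels == levels(y)[1]))

  full <- rpstack:::full_base_predictions(
    lapply(memo, function(s) s$fit(x, y)), memo, x, levels(y))
  expect_identical(full$provenance, "refit_full")
  expect_identical(as.character(full$hard_labels[, 1]), as.character(y))

  expect_error(oof_base_predictions(x, label_vector(rep("a", 48), c("a", "b")),
                                    memo, 4, 1),
               "stratification impossible")
  tiny_class <- label_vector(c(rep("a", 45), rep("b", 3)))
  expect_error(oof_base_predictions(x, tiny_class, memo, 4, 1), "fewer than inner_folds")
})

test_that("composite features append meta-features of the documented width", {
  n <- 12
  fused <- matrix(rnorm(n * 8000), n, 8000)  # m=20 blocks of k=400
  lv <- c("A", "B")
  fake_prob <- lapply(1:10, function(i) {
    p <- matrix(runif(n), n, 1)
    p <- cbind(p, 1 - p)
    colnames(p) <- lv
    p
  })
  names(fake_prob) <- paste0("M", 1:10)
  hard <- vapply(fake_prob, function(p) lv[max.col(p)], character(n))
  preds <- structure(list(probabilities = fake_prob, hard_labels = hard,
                          label_set = lv, provenance = "out_of_fold"),
                     class = "rps_base_predictions")

  comp <- build_composite(fused, preds, "hard_labels")
  expect_identical(ncol(comp), 8010L)
  expect_equal(comp[, 1:8000], fused, ignore_attr = TRUE)
  expect_true(all(comp[, 8001:8010] %in% c(0L, 1L)))

  prob_comp <- build_composite(fused, preds, "probabilities")
  expect_identical(ncol(prob_comp), 8020L)  # N*C = 20 meta columns

  empty <- structure(list(probabilities = list(), hard_labels = NULL,
                          label_set = lv), class = "rps_base_predictions")
  expect_identical(build_composite(fused, empty, "hard_labels"), fused)

  expect_error(build_composite(fused[1:5, ], preds, "hard_labels"), "row mismatch")
})

test_that("the meta-learner separates well-spaced blobs deterministically", {
  blobs <- make_blobs(n = 200, p = 12, separation = 6)
  meta <- fit_meta(blobs$x, blobs$y, epochs = 150, seed = 4)
  prob <- predict_meta(meta, blobs$x)
  expect_equal(rowSums(prob), rep(1, 200), tolerance = 1e-6, ignore_attr = TRUE)
  acc <- mean(colnames(prob)[max.col(prob)] == as.character(blobs$y))
  expect_gte(acc, 0.95)

  meta2 <- fit_meta(blobs$x, blobs$y, epochs = 150, seed = 4)
  expect_identical(predict_meta(meta2, blobs$x), prob)

  bad <- blobs$x; bad[1, 1] <- NA
  expect_error(fit_meta(bad, blobs$y), "non-finite")
})

test_that("the fitted classifier predicts consistently, realigns genes, and round-trips", {
  sim <- tiny_dataset(n = 60, d = 80)
  cfg <- rps_config(k = 15, m = 3, models = c("KNN-U", "RF-G", "XGB"),
                    inner_folds = 3, epochs = 120, seed = 5,
                    num_trees = 50, nrounds = 20)
  fit <- rps_fit(sim$X, sim$y, cfg)
  expect_identical(fit$rp_m, 3L)
  expect_identical(fit$rp_k, 15L)

  pred <- predict(fit, sim$X)
  expect_identical(as.character(pred$labels),
                   colnames(pred$prob)[max.col(pred$prob, ties.method = "first")])

  # identical seed and data give byte-identical held-out predictions
  fit2 <- rps_fit(sim$X, sim$y, cfg)
  expect_identical(predict(fit2, sim$X)$prob, pred$prob)

  # gene columns permuted (ids intact) must not change predictions
  perm <- sample(ncol(sim$X))
  Xperm <- unclass(sim$X)[, perm]
  expect_identical(predict(fit, Xperm)$prob, pred$prob)

  expect_error(predict(fit, unclass(sim$X)[, 1:50]), "lacks 30 training gene")

  arch <- tempfile(fileext = ".rds")
  rps_save(fit, arch)
  reloaded <- rps_load(arch)
  expect_identical(predict(reloaded, sim$X)$prob, pred$prob)

  expect_output(print(fit), "3 blocks of k = 15")
})

test_that("the score ensemble averages per-projection probabilities on the simplex", {
  sim <- tiny_dataset(n = 50, d = 60)
  cfg <- rps_config(k = 10, m = 1, seed = 3, nn_epochs = 40)
  one <- score_ensemble_fit_predict(sim$X, sim$y, cfg)
  # m = 1 reduces to the single NN run on that projection
  spec <- base_registry(seed = rpstack:::derive_seed(3, 12), models = "NN",
                        nn_epochs = 40)[[1]]
  R <- rp_matrix(60, 10, rpstack:::derive_seed(3, 11))
  proj <- rp_project(unclass(sim$X), R)
  direct <- spec$predict(spec$fit(proj, sim$y), proj)
  expect_equal(one$prob, direct, tolerance = 1e-12, ignore_attr = TRUE)

  cfg5 <- rps_config(k = 10, m = 5, seed = 3, nn_epochs = 40)
  five <- score_ensemble_fit_predict(sim$X, sim$y, cfg5)
  expect_equal(rowSums(five$prob), rep(1, 50), tolerance = 1e-6, ignore_attr = TRUE)
})
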