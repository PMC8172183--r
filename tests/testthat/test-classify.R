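test_that("stratified folds partition the rows and balance the classes", {
  y <- rep(c("a", "b", "c", "d"), each = 25)
  fold <- stratified_folds(y, 5, seed = 3)
  expect_equal(length(fold), 100)
  expect_equal(sort(unique(fold)), 1:5)
  # disjoint and exhaustive by construction; balanced within class
  for (cl in unique(y)) {
    expect_true(all(table(fold[y == cl]) == 5))
  }
  expect_identical(fold, stratified_folds(y, 5, seed = 3))
})

test_that("every classifier separates well-separated clusters", {
  feats <- gaussian_features(n_per_class = 40, d = 6, sep = 8, seed = 5)
  for (nm in c("svm", "knn")) {
    cv <- crossvalidate(feats, classifier_spec(nm), seed = 2)
    expect_equal(mean(cv$accuracy), 1.0)
  }
  for (nm in c("lda", "ridge", "random_forest", "dbn")) {
    cv <- crossvalidate(feats, classifier_spec(nm), seed = 2)
    expect_gt(mean(cv$accuracy), 0.9)
  }
  # discrete SAMME over depth-1 stumps resolves only a subset of one-vs-rest
  # boundaries on 4 classes; it must still be far above 0.25 chance
  ada <- crossvalidate(feats, classifier_spec("adaboost"), seed = 2)
  expect_gt(mean(ada$accuracy), 0.45)
})

test_that("cross-validation results are deterministic and respect group filters", {
  feats <- gaussian_features(n_per_class = 40, d = 5, sep = 1, seed = 6)
  a <- crossvalidate(feats, classifier_spec("lda"), seed = 4)
  b <- crossvalidate(feats, classifier_spec("lda"), seed = 4)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(nrow(a), 5)
  expect_true(all(a$accuracy >= 0 & a$accuracy <= 1))

  nurse <- crossvalidate(feats, classifier_spec("lda"), seed = 4,
                         group_filter = "nurse")
  expect_equal(length(attr(nurse, "fold_assignment")),
               sum(feats$group == "nurse"))

  few <- gaussian_features(n_per_class = 3, d = 4, seed = 1)
  expect_error(crossvalidate(few, classifier_spec("lda"), n_folds = 5), "at least")
})

test_that("fold-safe latent mode trains fold-specific autoencoders from one seed", {
  feats <- gaussian_features(n_per_class = 30, d = 6, sep = 2, seed = 7)
  cv <- crossvalidate(feats, classifier_spec("lda"), seed = 8,
                      ae_latent = TRUE, ae_arch = ae_architecture(6, c(8, 4)),
                      ae_hyper = list(max_epochs = 5))
  models <- attr(cv, "fold_models")
  expect_length(models, 5)
  # identical init seed, different training rows: weights must differ
  for (k in 2:5) {
    expect_false(isTRUE(all.equal(models[[1]]$W, models[[k]]$W)))
  }
  expect_equal(cv$representation, rep("latent", 5))

  # the global (leaky) variant trains a single shared autoencoder
  cvg <- crossvalidate(feats, classifier_spec("lda"), seed = 8,
                       ae_latent = TRUE, ae_arch = ae_architecture(6, c(8, 4)),
                       ae_hyper = list(max_epochs = 5), ae_global = TRUE)
  expect_null(attr(cvg, "fold_models"))
})

test_that("standardization statistics come from training folds only", {
  feats <- gaussian_features(n_per_class = 30, d = 4, sep = 3, seed = 9)
  fold <- stratified_folds(factor(feats$condition), 5, seed = 10)
  # plant a sentinel outlier in one of fold 5's rows. Fold 5's training rows
  # are unchanged, so with fold-safe standardization its fitted scaler and
  # model are identical to the clean run, and only the sentinel row's own
  # prediction can change: accuracy moves by at most 1/n_test. A scaler fitted
  # on all rows would shift every z-score in the fold and wreck it.
  clean <- crossvalidate(feats, classifier_spec("lda"), seed = 10)
  poisoned <- feats
  row5 <- which(fold == 5)[1]
  poisoned[row5, feature_cols(poisoned)] <- 1e6
  dirty <- crossvalidate(poisoned, classifier_spec("lda"), seed = 10)
  n5 <- sum(fold == 5)
  expect_lte(abs(dirty$accuracy[5] - clean$accuracy[5]), 1 / n5 + 1e-12)
})

test_that("run_benchmark enumerates sets x representations x classifiers", {
  sets <- list(
    power = gaussian_features(n_per_class = 20, d = 6, sep = 2, seed = 11),
    bli = gaussian_features(n_per_class = 20, d = 1, sep = 1, seed = 12)
  )
  clf <- list(lda = classifier_spec("lda"), ridge = classifier_spec("ridge"))
  res <- run_benchmark(sets, clf, n_folds = 5, seed = 13,
                       ae_arch = NULL, ae_hyper = list(max_epochs = 3))
  # 2 sets x 2 representations x 2 classifiers x 5 folds
  expect_equal(nrow(res), 40)
  expect_equal(
    nrow(dplyr::distinct(res, feature_set, representation, classifier)), 8
  )
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("report_benchmark summarises, sorts, flags the best and validates", {
  feats <- gaussian_features(n_per_class = 20, d = 5, sep = 2, seed = 14)
  one <- crossvalidate(feats, classifier_spec("lda"), seed = 1)
  rep1 <- report_benchmark(one)
  expect_equal(nrow(rep1), 1)
  expect_true(all(c("mean_accuracy", "mean_precision", "mean_f1", "best") %in%
                    names(rep1)))

  two <- dplyr::bind_rows(one, crossvalidate(feats, classifier_spec("knn"), seed = 1))
  rep2 <- report_benchmark(two)
  expect_equal(nrow(rep2), 2)
  # exactly the maximal rows are flagged best
  expect_equal(rep2$best, rep2$mean_accuracy == max(rep2$mean_accuracy))
  expect_true(all(diff(rep2$mean_accuracy) <= 0)) # sorted descending

  broken <- one
  broken$accuracy[2] <- NaN
  expect_error(report_benchmark(broken), "non-finite")
  expect_error(report_benchmark(one[0, ]), "empty")
})
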