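# The classifier bench. Each classifier is exposed through a uniform
# fit/predict pair keyed by name; standard algorithms come from their
# canonical packages (e1071, MASS, randomForest, class), AdaBoost (SAMME over
# rpart stumps), the ridge classifier and the small feedforward "dbn" adapter
# are implemented here.

#' Classifier specification
#'
#' @param name One of `"svm"`, `"adaboost"`, `"lda"`, `"ridge"`,
#'   `"random_forest"`, `"knn"`, `"dbn"`.
#' @param ... Hyperparameter overrides. Defaults: SVM — RBF kernel, cost 1,
#'   kernel width `1 / (d * mean feature variance)`; AdaBoost — depth-1
#'   decision-tree base learners, 50 boosting rounds; random forest — 100
#'   trees; KNN — `k = 5`, Minkowski distance with `p = 2` (Euclidean);
#'   LDA/ridge — standard defaults (ridge penalty `lambda = 1`); DBN adapter —
#'   two 64-unit ReLU layers trained by SGD on the softmax cross-entropy.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "adaboost", "lda", "ridge",
                                     "random_forest", "knn", "dbn"),
                            ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm = list(cost = 1),
    adaboost = list(n_estimators = 50, max_depth = 1),
    lda = list(),
    ridge = list(lambda = 1),
    random_forest = list(n_trees = 100),
    knn = list(k = 5),
    dbn = list(widths = c(64, 64), lr = 0.05, epochs = 30, batch_size = 32)
  )
  hyper <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyper = hyper), class = "classifier_spec")
}

#' The default deterministic classifier bench
#'
#' The six classifiers run by default: SVM, AdaBoost, LDA, ridge, random
#' forest and KNN. The DBN adapter can be appended with
#' `c(default_classifiers(), list(classifier_spec("dbn")))`.
#'
#' @return A named list of [classifier_spec()]s.
#' @export
default_classifiers <- function() {
  names <- c("svm", "adaboost", "lda", "ridge", "random_forest", "knn")
  setNames(map(names, classifier_spec), names)
}

# ---- fit/predict backends ---------------------------------------------------

fit_classifier <- function(spec, X, y) {
  y <- factor(y)
  h <- spec$hyper
  model <- switch(spec$name,
    svm = {
      gamma <- 1 / (ncol(X) * max(mean(apply(X, 2, var)), 1e-12))
      e1071::svm(X, y, kernel = "radial", cost = h$cost, gamma = gamma, scale = FALSE)
    },
    lda = fit_lda(X, y),
    random_forest = randomForest::randomForest(X, y, ntree = h$n_trees),
    knn = list(X = X, y = y, k = h$k),
    ridge = fit_ridge(X, y, h$lambda),
    adaboost = fit_samme(X, y, h$n_estimators, h$max_depth),
    dbn = fit_mlp(X, y, h$widths, h$lr, h$epochs, h$batch_size)
  )
  structure(list(name = spec$name, model = model, levels = levels(y)),
            class = "eeg_classifier")
}

predict_classifier <- function(fit, X) {
  out <- switch(fit$name,
    svm = as.character(predict(fit$model, X)),
    lda = as.character(predict(fit$model$fit, X[, fit$model$keep, drop = FALSE])$class),
    random_forest = as.character(predict(fit$model, X)),
    knn = as.character(class::knn(fit$model$X, X, fit$model$y, k = fit$model$k)),
    ridge = predict_ridge(fit$model, X),
    adaboost = predict_samme(fit$model, X),
    dbn = predict_mlp(fit$model, X)
  )
  factor(out, levels = fit$levels)
}

# LDA needs within-class variation in every column; latent ReLU codes can
# carry dead (constant) units, so those columns are dropped before fitting.
# Collinearity warnings are routine for overcomplete codes and muffled.
fit_lda <- function(X, y) {
  within_sd <- apply(X, 2, function(col) max(tapply(col, y, sd)))
  keep <- which(within_sd > 1e-10)
  if (length(keep) == 0) keep <- 1L
  fit <- withCallingHandlers(
    MASS::lda(X[, keep, drop = FALSE], grouping = y),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, keep = keep)
}

# one-vs-rest ridge regression on a +/-1 indicator matrix; predicted class is
# the column with the largest score
fit_ridge <- function(X, y, lambda) {
  classes <- levels(y)
  Y <- 2 * outer(as.character(y), classes, `==`) - 1
  X1 <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  B <- solve(crossprod(X1) + pen, crossprod(X1, Y))
  list(B = B, classes = classes)
}

predict_ridge <- function(m, X) {
  scores <- cbind(1, X) %*% m$B
  m$classes[max.col(scores, ties.method = "first")]
}

# multiclass AdaBoost (SAMME) with rpart stumps
fit_samme <- function(X, y, n_estimators, max_depth) {
  n <- length(y)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(
      y ~ ., data = df, weights = w,
      control = rpart::rpart.control(maxdepth = max_depth, cp = -1,
                                     minsplit = 2, xval = 0),
      method = "class"
    )
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break # no better than chance: stop boosting
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break # perfect stump: its vote dominates
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, classes = levels(y))
}

predict_samme <- function(m, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(df), length(m$classes), dimnames = list(NULL, m$classes))
  for (i in seq_along(m$stumps)) {
    pred <- as.character(predict(m$stumps[[i]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, m$classes))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, m$classes))] + m$alphas[i]
  }
  m$classes[max.col(votes, ties.method = "first")]
}

# small feedforward softmax network (the optional "dbn" adapter)
fit_mlp <- function(X, y, widths, lr, epochs, batch_size) {
  K <- nlevels(y)
  yi <- as.integer(y)
  dims <- c(ncol(X), widths, K)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1], -lim, lim), dims[l])
    b[[l]] <- numeric(dims[l + 1])
  }
  n <- nrow(X)
  L <- length(W)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      a <- list(X[idx, , drop = FALSE])
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
        a[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      p <- exp(a[[L + 1]] - apply(a[[L + 1]], 1, max))
      p <- p / rowSums(p)
      delta <- p
      delta[cbind(seq_along(idx), yi[idx])] <- delta[cbind(seq_along(idx), yi[idx])] - 1
      delta <- delta / length(idx)
      for (l in L:1) {
        dW <- crossprod(a[[l]], delta)
        db <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        W[[l]] <- W[[l]] - lr * dW
        b[[l]] <- b[[l]] - lr * db
      }
    }
  }
  list(W = W, b = b, classes = levels(y))
}

predict_mlp <- function(m, X) {
  a <- X
  L <- length(m$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% m$W[[l]], 2, m$b[[l]], `+`)
    a <- if (l < L) pmax(z, 0) else z
  }
  m$classes[max.col(a, ties.method = "first")]
}

# ---- cross-validation -------------------------------------------------------

#' Stratified fold assignment
#'
#' Within each class, shuffled rows are dealt round-robin to folds, so folds
#' are disjoint, exhaustive and class-balanced up to rounding.
#'
#' @param y Label vector.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:n_folds`, one per row of `y`.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

fold_metrics <- function(truth, pred) {
  classes <- levels(truth)
  acc <- mean(pred == truth)
  per_class <- map(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble(class = cl, precision = prec, recall = rec, f1 = f1)
  }) |> list_rbind()
  list(accuracy = acc, per_class = per_class)
}

#' Stratified k-fold cross-validation of one classifier on one feature set
#'
#' Folds are stratified over the four condition labels. All data-dependent
#' fitting is fold-safe: feature standardization (and, when `ae_latent =
#' TRUE`, the autoencoder) is fitted on the training folds only and applied to
#' the held-out fold.
#'
#' @param features A feature tibble with a `condition` column.
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds.
#' @param seed Integer seed (fold assignment and any stochastic fitting).
#' @param group_filter `"all"`, `"nurse"` or `"control"`.
#' @param ae_latent If `TRUE`, train an autoencoder on each training fold and
#'   classify the latent representation instead of the raw features.
#' @param ae_arch,ae_hyper Architecture and hyperparameter list
#'   (`lr`, `batch_size`, `max_epochs`, `patience`) for the fold autoencoders.
#' @param ae_global If `TRUE` (with `ae_latent`), train a single autoencoder
#'   on all rows before splitting — the optimistic, leaky variant, off by
#'   default.
#' @param standardize Z-score features (and latent codes) with training-fold
#'   statistics before classification.
#' @return A tibble of class `eeg_benchmark`, one row per fold, with columns
#'   `feature_set`, `representation`, `classifier`, `group_filter`, `fold`,
#'   `accuracy` and a `per_class` list-column of per-class precision/recall/F1.
#' @export
crossvalidate <- function(features, spec, n_folds = 5, seed = 1L,
                          group_filter = c("all", "nurse", "control"),
                          ae_latent = FALSE, ae_arch = NULL,
                          ae_hyper = list(), ae_global = FALSE,
                          standardize = TRUE) {
  group_filter <- match.arg(group_filter)
  if (group_filter != "all") features <- filter(features, .data$group == group_filter)
  y <- factor(features$condition)
  if (any(table(y) < n_folds)) {
    abort(sprintf("every class needs at least %d rows for %d-fold CV", n_folds, n_folds))
  }
  X <- feature_matrix(features)
  fold <- stratified_folds(y, n_folds, seed)
  hy <- utils::modifyList(
    list(lr = 0.01, batch_size = 32, max_epochs = 200, patience = 20), ae_hyper
  )
  global_model <- NULL
  if (ae_latent && ae_global) {
    global_model <- ae_train(X, arch = ae_arch, lr = hy$lr,
                             batch_size = hy$batch_size, max_epochs = hy$max_epochs,
                             patience = hy$patience, seed = seed)
  }

  fold_models <- vector("list", n_folds)
  rows <- map(seq_len(n_folds), function(k) {
    tr <- fold != k
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (any(table(y[tr]) == 0)) abort(sprintf("class absent from training fold %d", k))

    if (ae_latent) {
      model <- global_model %||% ae_train(
        Xtr, arch = ae_arch, lr = hy$lr, batch_size = hy$batch_size,
        max_epochs = hy$max_epochs, patience = hy$patience,
        seed = seed
      )
      fold_models[[k]] <<- model
      Xtr <- ae_encode(model, Xtr)
      Xte <- ae_encode(model, Xte)
    }
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, sd)
      sg[sg < 1e-12] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, `/`)
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, `/`)
    }
    fit <- with_seed(seed + k, fit_classifier(spec, Xtr, y[tr]))
    pred <- predict_classifier(fit, Xte)
    m <- fold_metrics(factor(y[!tr], levels = levels(y)), pred)
    tibble(fold = k, accuracy = m$accuracy, per_class = list(m$per_class))
  }) |> list_rbind()

  out <- mutate(rows,
    feature_set = attr(features, "feature_set") %||% "features",
    representation = if (ae_latent) "latent" else "raw",
    classifier = spec$name,
    group_filter = group_filter,
    n_folds = n_folds, seed = as.integer(seed),
    .before = 1
  )
  attr(out, "fold_assignment") <- fold
  if (ae_latent && !ae_global) attr(out, "fold_models") <- fold_models
  class(out) <- c("eeg_benchmark", class(out))
  out
}
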