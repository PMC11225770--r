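# Classifier bank and evaluation protocol.
#
# Seven classifiers behind one fit/predict contract: linear-kernel SVM,
# logistic regression, decision tree, Manhattan-distance kNN, random forest,
# gradient-boosted trees and Gaussian naive Bayes. The positive class
# (label 1, "paddy with pest") drives the TP/FP accounting. Metrics are on
# the 0-100 scale. Splitting is always stratified.

CLASSIFIER_KINDS <- c("svm", "logistic_regression", "decision_tree", "knn",
                      "random_forest", "xgb", "naive_bayes")

#' Specify a classifier
#'
#' @param kind one of `"svm"` (linear kernel), `"logistic_regression"`,
#'   `"decision_tree"`, `"knn"` (Manhattan distance), `"random_forest"`,
#'   `"xgb"`, `"naive_bayes"`.
#' @param hyperparameters named list of overrides for the wrapped learner's
#'   defaults (e.g. `list(k = 7)` for kNN, `list(nrounds = 50)` for xgb).
#'   Unknown names are rejected at fit time.
#' @param seed integer seed applied before every fit for reproducibility.
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(kind = "logistic_regression",
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

check_params <- function(given, allowed, kind) {
  bad <- setdiff(names(given), allowed)
  if (length(bad)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

as_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; stratification failed",
         call. = FALSE)
  }
  list(X = X, y = y)
}

#' Fit a classifier and predict test labels
#'
#' @param spec a [classifier_spec()].
#' @param X_train,y_train training feature matrix and 0/1 labels (both
#'   classes must be present).
#' @param X_test test feature matrix.
#' @return integer vector of 0/1 predictions, one per test row.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  d <- as_xy(X_train, y_train)
  X_test <- as.matrix(X_test)
  storage.mode(X_test) <- "double"
  hp <- spec$hyperparameters
  # fits own a private RNG stream so callers' streams are untouched
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  pred <- switch(spec$kind,
    svm = {
      check_params(hp, c("cost", "kernel"), "svm")
      fit <- e1071::svm(d$X, factor(d$y, levels = 0:1),
                        kernel = hp$kernel %||% "linear",
                        cost = hp$cost %||% 1, scale = FALSE)
      as.integer(as.character(stats::predict(fit, X_test)))
    },
    logistic_regression = {
      check_params(hp, character(0), "logistic_regression")
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, d$X), d$y, family = stats::binomial())
      )
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      as.integer(drop(cbind(1, X_test) %*% beta) > 0)
    },
    decision_tree = {
      check_params(hp, c("cp", "minsplit", "maxdepth"), "decision_tree")
      df <- data.frame(y = factor(d$y, levels = 0:1), d$X)
      ctl <- rpart::rpart.control(cp = hp$cp %||% 0.01,
                                  minsplit = hp$minsplit %||% 20,
                                  maxdepth = hp$maxdepth %||% 30)
      fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctl)
      newdf <- data.frame(X_test)
      colnames(newdf) <- colnames(df)[-1]
      as.integer(as.character(stats::predict(fit, newdf, type = "class")))
    },
    knn = {
      check_params(hp, "k", "knn")
      knn_manhattan(d$X, d$y, X_test, k = hp$k %||% 5L)
    },
    random_forest = {
      check_params(hp, c("ntree", "mtry"), "random_forest")
      args <- list(x = d$X, y = factor(d$y, levels = 0:1),
                   ntree = hp$ntree %||% 500)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      fit <- do.call(randomForest::randomForest, args)
      as.integer(as.character(stats::predict(fit, X_test)))
    },
    xgb = {
      check_params(hp, c("nrounds", "max_depth", "eta"), "xgb")
      dtrain <- xgboost::xgb.DMatrix(d$X, label = d$y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 6,
                      eta = hp$eta %||% 0.3,
                      seed = spec$seed, nthread = 1),
        data = dtrain, nrounds = hp$nrounds %||% 100, verbose = 0
      )
      dtest <- xgboost::xgb.DMatrix(X_test, nthread = 1)
      as.integer(stats::predict(fit, dtest) > 0.5)
    },
    naive_bayes = {
      check_params(hp, "laplace", "naive_bayes")
      fit <- e1071::naiveBayes(d$X, factor(d$y, levels = 0:1),
                               laplace = hp$laplace %||% 0)
      as.integer(as.character(stats::predict(fit, X_test)))
    }
  )
  pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Manhattan (L1) distance between two points
#'
#' @param a,b numeric vectors of equal length.
#' @return the L1 distance `sum(|a - b|)`.
#' @export
manhattan_distance <- function(a, b) sum(abs(a - b))

# k-nearest-neighbour vote under the L1 metric; ties in the vote go to the
# single nearest neighbour's label (k odd avoids them for binary labels)
knn_manhattan <- function(X_train, y_train, X_test, k = 5L) {
  k <- min(as.integer(k), nrow(X_train))
  # full test x train L1 distance matrix, accumulated one feature at a time
  D <- matrix(0, nrow(X_test), nrow(X_train))
  for (j in seq_len(ncol(X_train))) {
    D <- D + abs(outer(X_test[, j], X_train[, j], "-"))
  }
  vapply(seq_len(nrow(X_test)), function(i) {
    ord <- order(D[i, ], seq_len(ncol(D)))
    nn <- y_train[ord[seq_len(k)]]
    votes1 <- sum(nn == 1L)
    if (votes1 * 2L == k) return(nn[1L])
    as.integer(votes1 * 2L > k)
  }, integer(1))
}

#' Confusion counts for binary predictions
#'
#' Label 1 ("with pest") is the positive class.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(
    TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L)
  ), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' All four metrics are reported on the 0-100 scale:
#' `A = (TP+TN)/(TP+TN+FP+FN) * 100`, `P = TP/(TP+FP) * 100`,
#' `R = TP/(TP+FN) * 100`, `F1 = 2 P R / (P + R)`. A zero denominator yields
#' 0 with a warning rather than an error, so report grids never abort.
#'
#' @param counts a [confusion_counts()] object or a list with TP/TN/FP/FN.
#' @return a `metrics_report` list with `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
compute_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("no evaluated samples: all confusion counts are zero")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s has a zero denominator; reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  a <- (counts$TP + counts$TN) / n * 100
  p <- safe_ratio(counts$TP, counts$TP + counts$FP, "precision") * 100
  r <- safe_ratio(counts$TP, counts$TP + counts$FN, "recall") * 100
  f1 <- if (p + r == 0) {
    warning("F1 has a zero denominator; reporting 0", call. = FALSE)
    0
  } else 2 * p * r / (p + r)
  structure(list(accuracy = a, precision = p, recall = r, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f | precision %.2f | recall %.2f | F1 %.2f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stratified holdout split
#'
#' @param y 0/1 labels.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.8).
#' @param seed integer seed.
#' @return `list(train =, test =)` of disjoint, exhaustive row indices with
#'   per-class ratios preserved within rounding.
#' @export
holdout_split <- function(y, train_fraction = 0.8, seed = 1L) {
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("both classes must be present")
  if (any(tabulate(match(y, classes)) < 2L)) {
    stop("each class needs at least 2 samples for a stratified split")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in classes) {
    idx <- which(y == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Stratified k-fold assignment
#'
#' @param y 0/1 labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1:folds`, one per sample; each
#'   fold's class ratio is within one sample of the global ratio.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (folds > length(y)) stop("more folds than samples")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  assignment <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Stratified k-fold cross-validation of one classifier
#'
#' @param spec a [classifier_spec()].
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `per_fold` (a data.frame of the four metrics per fold)
#'   and `mean` (their unweighted mean as a `metrics_report`).
#' @export
cross_validate <- function(spec, X, y, folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  assignment <- stratified_folds(y, folds, seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(assignment == f); tr <- which(assignment != f)
    pred <- fit_predict(spec, X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    m <- compute_metrics(confusion_counts(y[te], pred))
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  mean_rep <- structure(as.list(colMeans(per_fold[, -1])),
                        class = "metrics_report")
  list(per_fold = per_fold, mean = mean_rep)
}
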