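# Dimensionality reduction and feature selection over feature tables:
# PCA (1/n covariance), LDA (scatter-matrix eigendecomposition), RFE
# (recursive elimination under a wrapped model's importances) and the
# lion-optimizer binary wrapper selector.

check_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L || ncol(X) < 1L) stop("feature matrix must be at least 2 x 1")
  if (!all(is.finite(X))) stop("feature matrix contains non-finite entries")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Principal component analysis with population-normalized covariance
#'
#' Computes the covariance with the 1/n normalization
#' `sigma_jk = (1/n) * sum_i (x_j(i) - mu_j)(x_k(i) - mu_k)` (the population
#' form, not the 1/(n-1) sample form), eigendecomposes it, and projects the
#' centered data on the top-k eigenvectors.
#'
#' @param X an n x d feature matrix.
#' @param k number of components, `1 <= k <= d`.
#' @return a `pca_model`: `means`, `covariance`, `components` (d x k,
#'   orthonormal), `explained_variance` (descending eigenvalues, length k)
#'   and `reduced` (n x k projected data).
#' @export
pca_reduce <- function(X, k) {
  X <- check_feature_matrix(X)
  d <- ncol(X)
  if (k < 1L || k > d) stop("k must be between 1 and the number of features")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covmat <- crossprod(Xc) / nrow(X)
  eig <- eigen(covmat, symmetric = TRUE)
  comps <- eig$vectors[, seq_len(k), drop = FALSE]
  structure(list(
    means = mu, covariance = covmat, components = comps,
    explained_variance = pmax(eig$values[seq_len(k)], 0),
    reduced = Xc %*% comps
  ), class = "pca_model")
}

#' Linear discriminant analysis via scatter matrices
#'
#' The five-step procedure: per-class mean vectors; within-class and
#' between-class scatter matrices; eigendecomposition of
#' `solve(Sw) %*% Sb` (with `Sw` ridge-regularized by
#' `1e-6 * trace(Sw)/d * I`, since deep-feature tables routinely have
#' `d >> n`); eigenvectors sorted by decreasing eigenvalue; and the
#' projection `Y = X %*% W` on the top-k directions. For B classes at most
#' B-1 directions carry signal.
#'
#' @param X an n x d feature matrix.
#' @param y class labels (both classes present).
#' @param k number of discriminant directions, `k <= d`.
#' @param ridge regularization scale for the within-class scatter.
#' @return an `lda_model`: `class_means`, `within_scatter`,
#'   `between_scatter`, `eigenvalues` (descending), `projection` (d x k) and
#'   `projected` (n x k).
#' @export
lda_reduce <- function(X, y, k, ridge = 1e-6) {
  X <- check_feature_matrix(X)
  y <- as.integer(y)
  d <- ncol(X)
  if (k < 1L || k > d) stop("k must be between 1 and the number of features")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("both classes must be present")
  overall <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  class_means <- matrix(NA_real_, length(classes), d,
                        dimnames = list(classes, colnames(X)))
  for (ci in seq_along(classes)) {
    rows <- X[y == classes[ci], , drop = FALSE]
    mc <- colMeans(rows)
    class_means[ci, ] <- mc
    dev <- sweep(rows, 2, mc)
    Sw <- Sw + crossprod(dev)
    Sb <- Sb + nrow(rows) * tcrossprod(mc - overall)
  }
  Sw_reg <- Sw + diag(ridge * sum(diag(Sw)) / d, d)
  eig <- eigen(solve(Sw_reg, Sb))
  lambda <- Re(eig$values)
  ord <- order(lambda, decreasing = TRUE)
  W <- Re(eig$vectors[, ord[seq_len(k)], drop = FALSE])
  structure(list(
    class_means = class_means, within_scatter = Sw, between_scatter = Sb,
    eigenvalues = lambda[ord], projection = W, projected = X %*% W
  ), class = "lda_model")
}

new_selection_mask <- function(mask, source, feature_names) {
  mask <- as.integer(mask)
  if (sum(mask) < 1L) stop("a selection mask must retain at least one feature")
  structure(list(mask = mask, selected_count = sum(mask), source = source,
                 feature_names = feature_names),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask (%s): %d of %d features retained\n",
              x$source, x$selected_count, length(x$mask)))
  invisible(x)
}

#' Write a selection mask as delimited text
#'
#' @param mask a `selection_mask`.
#' @param path output file; tab-separated `feature_name`, `selected` columns.
#' @return `path`, invisibly.
#' @export
write_selection_mask <- function(mask, path) {
  utils::write.table(
    data.frame(feature_name = mask$feature_names, selected = mask$mask),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# per-feature importances for the models RFE supports
feature_importance <- function(spec, X, y) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  switch(spec$kind,
    logistic_regression = {
      sds <- apply(X, 2, stats::sd)
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial())
      )
      beta <- ifelse(is.na(fit$coefficients[-1]), 0, fit$coefficients[-1])
      (beta * sds)^2
    },
    svm = {
      fit <- e1071::svm(X, factor(y, levels = 0:1), kernel = "linear",
                        scale = FALSE)
      drop(crossprod(fit$coefs, fit$SV))^2
    },
    random_forest = {
      fit <- randomForest::randomForest(X, factor(y, levels = 0:1),
                                        importance = FALSE)
      drop(randomForest::importance(fit)[, 1])
    },
    stop(sprintf("classifier kind '%s' exposes no per-feature importance; RFE supports svm, logistic_regression and random_forest",
                 spec$kind), call. = FALSE)
  )
}

#' Recursive feature elimination
#'
#' Repeatedly fits the wrapped classifier and removes the single feature with
#' the lowest importance (squared linear weights for linear models) until
#' `n_keep` features remain. Survivor sets are nested across decreasing
#' `n_keep` for a fixed classifier seed.
#'
#' @param X an n x d feature matrix.
#' @param y 0/1 labels.
#' @param classifier a [classifier_spec()] exposing importances (`svm`,
#'   `logistic_regression` or `random_forest`).
#' @param n_keep number of features to retain.
#' @return a `selection_mask` with the elimination order (feature indices,
#'   first removed first) in `attr(, "elimination_order")`.
#' @export
rfe_select <- function(X, y, classifier = classifier_spec("logistic_regression"),
                       n_keep) {
  X <- check_feature_matrix(X)
  y <- as.integer(y)
  d <- ncol(X)
  if (n_keep < 1L || n_keep > d) stop("n_keep must be between 1 and d")
  alive <- seq_len(d)
  eliminated <- integer(0)
  while (length(alive) > n_keep) {
    imp <- feature_importance(classifier, X[, alive, drop = FALSE], y)
    worst <- alive[order(imp, alive)][1L]
    eliminated <- c(eliminated, worst)
    alive <- setdiff(alive, worst)
  }
  mask <- integer(d); mask[alive] <- 1L
  out <- new_selection_mask(mask, "rfe", colnames(X))
  attr(out, "elimination_order") <- eliminated
  out
}

#' Decode an optimizer position into a feature mask
#'
#' A coordinate above 0.5 selects the feature. If no coordinate clears the
#' threshold, the single largest coordinate is selected as a guard.
#'
#' @param position numeric vector in `[0,1]^d`.
#' @return integer 0/1 vector of length d with at least one 1.
#' @export
decode_mask <- function(position) {
  mask <- as.integer(position > 0.5)
  if (sum(mask) == 0L) mask[which.max(position)] <- 1L
  mask
}

#' Wrapper cross-validation error of a feature mask
#'
#' The exact quantity the lion selector minimizes: 1 minus the stratified
#' k-fold accuracy (0-1 scale) of the wrapped classifier on the masked
#' features, plus `lambda * selected/d`.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param mask integer/logical mask of length d with at least one 1.
#' @param classifier a [classifier_spec()].
#' @param folds internal CV folds (default 5).
#' @param seed seed for the fold assignments (fix it to make the error a pure
#'   function of the mask).
#' @param lambda sparsity weight (default 0: pure wrapper error).
#' @param repeats number of repeated fold assignments averaged (default 3).
#'   A single assignment lets the search adapt to one particular split and
#'   report a spuriously zero error; averaging over a few independent
#'   assignments makes the fitness a far more stable ranking of masks.
#' @return the scalar fitness value.
#' @export
wrapper_cv_error <- function(X, y, mask, classifier = classifier_spec(),
                             folds = 5L, seed = 1L, lambda = 0,
                             repeats = 3L) {
  mask <- as.logical(mask)
  Xm <- X[, mask, drop = FALSE]
  y <- as.integer(y)
  # plain misclassification rate (identical to 1 - accuracy/100), computed
  # directly: mid-search masks routinely yield degenerate folds, which the
  # full metric report would flag but the wrapper error absorbs silently
  err <- mean(vapply(seq_len(repeats), function(r) {
    assignment <- stratified_folds(y, folds, seed + (r - 1L) * 1000L)
    mean(vapply(seq_len(folds), function(f) {
      te <- which(assignment == f); tr <- which(assignment != f)
      pred <- fit_predict(classifier, Xm[tr, , drop = FALSE], y[tr],
                          Xm[te, , drop = FALSE])
      mean(pred != y[te])
    }, numeric(1)))
  }, numeric(1)))
  err + lambda * sum(mask) / ncol(X)
}

#' Lion-optimizer wrapper feature selection
#'
#' Runs the lion optimizer over `[0,1]^d`; positions decode to binary masks
#' via the 0.5 threshold ([decode_mask()]) and the fitness of a mask is its
#' stratified internal-CV error under the wrapped classifier
#' ([wrapper_cv_error()]), optionally plus a sparsity term. The fold
#' assignment and classifier seed are fixed once per call, so the fitness is
#' a pure function of the mask (and is memoised across repeated
#' evaluations); identical seeds reproduce the selection bit-exactly.
#'
#' @param X an n x d feature matrix, `d >= 2`.
#' @param y 0/1 labels.
#' @param classifier a [classifier_spec()] used inside the wrapper; the
#'   default is the Manhattan-distance kNN. Distance-based classifiers make
#'   good wrapper drivers here: every retained noise feature corrupts the
#'   metric, so the CV error keeps ranking masks even when a linear model
#'   would already separate the classes perfectly.
#' @param config an [loa_config()] for the search; if `NULL`, a selection
#'   default of 30 lions in 3 prides for up to 40 iterations (patience 15)
#'   with the study's pride/nomad/mating ratios is used.
#' @param folds internal CV folds.
#' @param lambda sparsity weight on `selected/d` (default 0).
#' @param seed seed controlling the optimizer and the internal folds when
#'   `config` is `NULL`.
#' @return a list: `mask` (a `selection_mask`, source `"loa"`),
#'   `best_fitness` (the wrapper CV error of the returned mask), and
#'   `result` (the full `loa_result`).
#' @export
loa_select <- function(X, y, classifier = classifier_spec("knn"),
                       config = NULL, folds = 5L, lambda = 0, seed = 1L) {
  X <- check_feature_matrix(X)
  y <- as.integer(y)
  d <- ncol(X)
  if (d < 2L) stop("loa_select needs at least 2 features")
  if (is.null(config)) {
    config <- loa_config(nvar = d, population_size = 30L, num_prides = 3L,
                         max_iterations = 40L, patience = 15L,
                         lower_bounds = 0, upper_bounds = 1, seed = seed)
  }
  if (config$nvar != d) stop("config$nvar must equal ncol(X)")
  fold_seed <- config$seed + 1L
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    mask <- decode_mask(pos)
    key <- paste(mask, collapse = "")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    f <- wrapper_cv_error(X, y, mask, classifier, folds = folds,
                          seed = fold_seed, lambda = lambda)
    assign(key, f, envir = cache)
    f
  }
  res <- loa_optimize(objective, config)
  mask <- new_selection_mask(decode_mask(res$best_position), "loa", colnames(X))
  list(mask = mask, best_fitness = res$best_fitness, result = res)
}
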