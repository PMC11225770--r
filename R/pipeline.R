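# End-to-end orchestration: images -> filter (-> augment) -> deep features
# -> feature selection -> classifier grid -> report. A single top-level seed
# fans out to fixed per-stage offsets (+1 preprocess, +2 extract, +3 select,
# +4 classify) so each stage is independently reproducible.

SELECTOR_CHOICES <- c("none", "pca", "lda", "rfe", "loa",
                      "pca+loa", "lda+loa", "rfe+loa")

#' Pipeline run configuration
#'
#' @param images image input: a directory of PNGs (class per subdirectory),
#'   or a list with `images` and `labels` (e.g. [generate_toy_images()]).
#'   Ignored when `features` is given.
#' @param features feature-table input: a path readable by
#'   [read_feature_table()] or a list with `X` and `y`. Skips the
#'   preprocess/extract stages.
#' @param filter `NULL` to skip filtering, else a list with `kind`
#'   (`"median"`, `"gaussian"`, `"average"`), `size` and optionally `sigma`.
#' @param augment `NULL` to skip augmentation, else an [augment_spec()];
#'   augmented copies join the dataset with their source image's label.
#' @param backbone a [backbone_spec()].
#' @param selector one of `"none"`, `"pca"`, `"lda"`, `"rfe"`, `"loa"`, or a
#'   chained `"pca+loa"`, `"lda+loa"`, `"rfe+loa"` (classical stage first,
#'   lion wrapper on its output).
#' @param selector_args list of selector parameters: `k` (components for
#'   pca/lda), `n_keep` (rfe), `lambda` and `folds` (loa), `classifier`
#'   (wrapped [classifier_spec()] for rfe/loa).
#' @param classifiers character vector of classifier kinds or a list of
#'   [classifier_spec()] objects for the evaluation grid.
#' @param protocol `"holdout"` (stratified 80/20), `"cv"` (stratified 5-fold
#'   on the full table) or `"both"`.
#' @param train_fraction holdout training fraction.
#' @param folds cross-validation fold count.
#' @param loa an [loa_config()] for the `"loa"` selector, or `NULL` for the
#'   selection defaults of [loa_select()].
#' @param seed top-level seed.
#' @param output_dir if non-`NULL`, [write_run_report()] is called there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(images = NULL, features = NULL,
                            filter = list(kind = "median", size = 3L),
                            augment = NULL,
                            backbone = backbone_spec("mock"),
                            selector = "none", selector_args = list(),
                            classifiers = "logistic_regression",
                            protocol = c("holdout", "cv", "both"),
                            train_fraction = 0.8, folds = 5L,
                            loa = NULL, seed = 1L, output_dir = NULL) {
  selector <- match.arg(selector, SELECTOR_CHOICES)
  protocol <- match.arg(protocol)
  if (is.null(images) && is.null(features)) {
    stop("pipeline needs either 'images' or 'features' input")
  }
  if (is.character(classifiers)) {
    classifiers <- lapply(classifiers, function(k)
      classifier_spec(k, seed = seed + 4L))
  }
  structure(list(images = images, features = features, filter = filter,
                 augment = augment, backbone = backbone, selector = selector,
                 selector_args = selector_args, classifiers = classifiers,
                 protocol = protocol, train_fraction = train_fraction,
                 folds = as.integer(folds), loa = loa, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `backbone`
#' may be a name or a `name`/`output_dim` mapping.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$backbone)) {
    raw$backbone <- if (is.character(raw$backbone)) backbone_spec(raw$backbone)
      else do.call(backbone_spec, raw$backbone)
  }
  if (!is.null(raw$augment)) raw$augment <- do.call(augment_spec, raw$augment)
  if (!is.null(raw$loa)) raw$loa <- do.call(loa_config, raw$loa)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  clean <- unclass(config)
  clean$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(clean, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

apply_selector <- function(X, y, selector, args, loa_cfg, seed) {
  out <- list(X = X, selected_count = ncol(X), mask = NULL, loa_trace = NULL)
  parts <- strsplit(selector, "+", fixed = TRUE)[[1]]
  for (part in parts) {
    if (part == "none") next
    if (part == "pca") {
      k <- args$k %||% min(10L, ncol(out$X))
      out$X <- pca_reduce(out$X, k)$reduced
      colnames(out$X) <- paste0("pc", seq_len(ncol(out$X)))
      out$selected_count <- ncol(out$X)
    } else if (part == "lda") {
      k <- args$k %||% 1L
      out$X <- lda_reduce(out$X, y, k)$projected
      colnames(out$X) <- paste0("ld", seq_len(ncol(out$X)))
      out$selected_count <- ncol(out$X)
    } else if (part == "rfe") {
      n_keep <- args$n_keep %||% max(1L, ncol(out$X) %/% 2L)
      clf <- args$classifier %||% classifier_spec(seed = seed)
      mask <- rfe_select(out$X, y, clf, n_keep)
      out$X <- out$X[, mask$mask == 1L, drop = FALSE]
      out$mask <- mask
      out$selected_count <- mask$selected_count
    } else if (part == "loa") {
      clf <- args$classifier %||% classifier_spec("knn", seed = seed)
      cfg <- loa_cfg
      if (!is.null(cfg) && cfg$nvar != ncol(out$X)) cfg <- NULL
      sel <- loa_select(out$X, y, classifier = clf, config = cfg,
                        folds = args$folds %||% 5L,
                        lambda = args$lambda %||% 0, seed = seed)
      out$X <- out$X[, sel$mask$mask == 1L, drop = FALSE]
      out$mask <- sel$mask
      out$selected_count <- sel$mask$selected_count
      out$loa_trace <- sel$result$trace
    }
  }
  out
}

#' Run the full pipeline
#'
#' Executes the requested stages in order (preprocess, extract, select,
#' classify) on image or feature-table input and returns a run report whose
#' metrics grid has one row per (classifier, protocol) cell. Identical
#' config + seed reproduces the grid exactly.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: `grid` (data.frame with classifier, protocol and
#'   the four metrics), `selected_count`, `mask`, `loa_trace`,
#'   `augmented_count` and a `provenance` block (config hash, seed,
#'   timestamp).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (!is.null(config$features)) {
    feats <- if (is.character(config$features)) {
      if (!file.exists(config$features)) {
        stop("feature table not found: ", config$features)
      }
      read_feature_table(config$features)
    } else config$features
    X <- check_feature_matrix(feats$X); y <- as.integer(feats$y)
    augmented_count <- 0L
  } else {
    imgset <- if (is.character(config$images)) {
      if (!dir.exists(config$images)) stop("image directory not found: ",
                                           config$images)
      read_image_tree(config$images)
    } else config$images
    images <- imgset$images
    labels <- as.integer(imgset$labels)
    # preprocess (stage seed +1 reserved; filtering is deterministic)
    if (!is.null(config$filter)) {
      f <- config$filter
      images <- lapply(images, apply_filter, kind = f$kind,
                       size = f$size %||% 3L, sigma = f$sigma %||% 1)
    }
    augmented_count <- 0L
    if (!is.null(config$augment)) {
      extra <- list(); extra_lab <- integer(0)
      for (i in seq_along(images)) {
        aug <- augment(images[[i]], config$augment)
        extra <- c(extra, aug)
        extra_lab <- c(extra_lab, rep(labels[i], length(aug)))
      }
      augmented_count <- length(extra)
      images <- c(images, extra)
      labels <- c(labels, extra_lab)
    }
    X <- extract_features(images, config$backbone)
    y <- labels
  }

  sel <- apply_selector(X, y, config$selector, config$selector_args,
                        config$loa, seed + 3L)

  rows <- list()
  for (spec in config$classifiers) {
    if (config$protocol %in% c("holdout", "both")) {
      split <- holdout_split(y, config$train_fraction, seed = seed + 4L)
      pred <- fit_predict(spec, sel$X[split$train, , drop = FALSE],
                          y[split$train], sel$X[split$test, , drop = FALSE])
      m <- compute_metrics(confusion_counts(y[split$test], pred))
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = spec$kind, protocol = "holdout",
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, f1 = m$f1)
    }
    if (config$protocol %in% c("cv", "both")) {
      cv <- cross_validate(spec, sel$X, y, folds = config$folds,
                           seed = seed + 4L)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = spec$kind, protocol = sprintf("cv%d", config$folds),
        accuracy = cv$mean$accuracy, precision = cv$mean$precision,
        recall = cv$mean$recall, f1 = cv$mean$f1)
    }
  }
  grid <- do.call(rbind, rows)

  report <- structure(list(
    grid = grid,
    selected_count = sel$selected_count,
    mask = sel$mask,
    loa_trace = sel$loa_trace,
    augmented_count = augmented_count,
    n_samples = length(y), n_features = ncol(X),
    provenance = list(config_hash = config_hash(config), seed = seed,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "run_report")

  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' Best cell of a run report's metrics grid
#'
#' @param report a `run_report`.
#' @return the grid row with the highest accuracy.
#' @export
best_cell <- function(report) {
  report$grid[which.max(report$grid$accuracy), , drop = FALSE]
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (%d samples, %d features, %d selected)\n",
              x$n_samples, x$n_features, x$selected_count))
  print(x$grid, row.names = FALSE)
  b <- best_cell(x)
  cat(sprintf("best: %s / %s at accuracy %.2f\n",
              b$classifier, b$protocol, b$accuracy))
  invisible(x)
}

#' Write a run report as delimited text
#'
#' Writes `metrics_grid.tsv` (rows = classifier/protocol cells, columns =
#' the four metrics), `summary.txt` and, when present, the selection mask
#' and lion-optimizer trace.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$grid, file.path(dir, "metrics_grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$mask)) {
    write_selection_mask(report$mask, file.path(dir, "selection_mask.tsv"))
  }
  if (!is.null(report$loa_trace)) {
    utils::write.table(report$loa_trace, file.path(dir, "loa_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  b <- best_cell(report)
  writeLines(c(
    sprintf("samples: %d", report$n_samples),
    sprintf("features: %d (selected: %d)", report$n_features,
            report$selected_count),
    sprintf("augmented images added: %d", report$augmented_count),
    sprintf("best cell: %s / %s accuracy %.2f precision %.2f recall %.2f f1 %.2f",
            b$classifier, b$protocol, b$accuracy, b$precision, b$recall, b$f1),
    sprintf("config hash: %s", report$provenance$config_hash),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("timestamp: %s", report$provenance$timestamp)
  ), file.path(dir, "summary.txt"))
  invisible(dir)
}
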