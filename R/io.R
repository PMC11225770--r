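# Delimited-text and PNG input/output for feature tables, masks and image
# trees (one subdirectory per class, "no" -> 0 and "yes" -> 1).

#' Write a feature table with labels as delimited text
#'
#' Tab-separated, header row of feature names, final `label` column.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(X, y, path) {
  df <- as.data.frame(X)
  df$label <- as.integer(y)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input file.
#' @return list with `X` (numeric matrix) and `y` (integer labels).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature table needs a 'label' column")
  y <- as.integer(df$label)
  X <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

img_to_png_array <- function(img) {
  a <- if (length(dim(img)) == 3L) img else array(img, c(dim(img), 1L))
  a / 255
}

#' Write an image matrix/array as PNG
#'
#' @param img H x W matrix or H x W x C array in [0,255].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img_to_png_array(clip_image(img)), path)
  invisible(path)
}

#' Read a PNG as an image matrix/array in [0,255]
#'
#' Alpha channels are dropped; single-channel images come back as matrices.
#'
#' @param path PNG file.
#' @return H x W matrix or H x W x 3 array.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- a[, , 1:3] else a <- a[, , 1]
  }
  a * 255
}

#' Read a class-per-subdirectory PNG tree
#'
#' Subdirectory names map to labels: `"no"` (or `"no_pest"`, `"without"`
#' prefixes) to 0, anything else to 1, matching the yes/no class layout of
#' two-class pest datasets.
#'
#' @param dir root directory with one subdirectory per class.
#' @return list with `images`, `labels`, `paths`.
#' @export
read_image_tree <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) == 0L) stop("no class subdirectories under ", dir)
  images <- list(); labels <- integer(0); paths <- character(0)
  for (cl in classes) {
    lab <- if (grepl("^(no|without)", basename(cl), ignore.case = TRUE)) 0L else 1L
    files <- sort(list.files(cl, pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_image_png(f)
      labels <- c(labels, lab)
      paths <- c(paths, f)
    }
  }
  list(images = images, labels = labels, paths = paths)
}

#' Materialize a toy image set as a PNG tree
#'
#' @param toy output of [generate_toy_images()].
#' @param dir output directory; `yes`/`no` subdirectories are created.
#' @return `dir`, invisibly.
#' @export
write_image_tree <- function(toy, dir) {
  for (sub in c("yes", "no")) dir.create(file.path(dir, sub),
                                         recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(toy$images)) {
    sub <- if (toy$labels[i] == 1L) "yes" else "no"
    write_image_png(toy$images[[i]],
                    file.path(dir, sub, sprintf("img%04d.png", i)))
  }
  invisible(dir)
}
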