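# Pluggable deep-feature extraction: every backbone maps an image to a
# fixed-length real vector after resizing to 224 x 224 x 3. The "mock"
# backbone is a deterministic, weight-free extractor built from pooled
# intensity statistics (per-channel quantiles plus patch-grid moments) so
# the downstream selection and classification machinery is testable without
# pretrained CNN weights.

REAL_BACKBONES <- c(vgg16 = 4096L, vgg19 = 4096L, resnet50 = 2048L,
                    inceptionv3 = 2048L, xception = 2048L)

#' Specify a feature-extraction backbone
#'
#' Real backbone names are accepted and carry the published dimension of
#' their penultimate (pooled) layer, but extraction with them requires an
#' optional deep-learning toolchain that this package does not bundle; the
#' `"mock"` backbone is always available and fully deterministic.
#'
#' @param name one of `"mock"`, `"vgg16"`, `"vgg19"`, `"resnet50"`,
#'   `"inceptionv3"`, `"xception"`.
#' @param output_dim feature-vector length; configurable for the mock
#'   backbone only (default 256, at most 483 — the pooled-statistics
#'   budget of its quantile and patch blocks).
#' @return a `backbone_spec` list with `name`, `input_size` (224, 224, 3)
#'   and `output_dim`.
#' @export
backbone_spec <- function(name = "mock", output_dim = NULL) {
  name <- match.arg(name, c("mock", names(REAL_BACKBONES)))
  if (name == "mock") {
    output_dim <- as.integer(output_dim %||% 256L)
    if (output_dim < 1L || output_dim > mock_max_dim()) {
      stop(sprintf("mock output_dim must be between 1 and %d", mock_max_dim()))
    }
  } else {
    fixed <- REAL_BACKBONES[[name]]
    if (!is.null(output_dim) && as.integer(output_dim) != fixed) {
      stop(sprintf("output_dim of %s is fixed at %d by its architecture",
                   name, fixed))
    }
    output_dim <- fixed
  }
  structure(list(name = name, input_size = c(224L, 224L, 3L),
                 output_dim = output_dim),
            class = "backbone_spec")
}

#' Bilinear image resize
#'
#' @param img H x W matrix or H x W x C array.
#' @param height,width target size.
#' @return the resized image.
#' @export
resize_image <- function(img, height, width) {
  rs1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h == height && w == width) return(m)
    yy <- if (height == 1L) rep((h + 1) / 2, 1) else seq(1, h, length.out = height)
    xx <- if (width == 1L) rep((w + 1) / 2, 1) else seq(1, w, length.out = width)
    grid <- expand.grid(y = yy, x = xx)
    matrix(bilinear_sample(m, grid$y, grid$x, fill = 0), height, width)
  }
  per_channel(img, rs1)
}

to_rgb <- function(img) {
  if (length(dim(img)) == 3L) return(img[, , 1:3, drop = FALSE])
  array(rep(img, 3), c(dim(img), 3L))
}

# The mock feature vector concatenates two pooled-statistics blocks and
# truncates to output_dim, mimicking what CNN embeddings provide without
# weights:
#   1. a translation-invariant block: per-channel intensity quantiles,
#      interleaved probability-major so any prefix covers the full intensity
#      distribution coarsely (global pooling is position-invariant, which is
#      what lets small dark objects be detected wherever they sit);
#   2. a spatial block: mean and standard deviation of each cell of an
#      8 x 8 patch grid per channel (local feature-map statistics).
# A dense random projection of the statistics was deliberately rejected:
# randomly signed mixtures turn a consistent one-sided intensity shift into
# class variance once object positions vary, destroying separability.
MOCK_QUANTILE_PROBS <- seq(0.02, 0.98, length.out = 33)

mock_max_dim <- function(grid = 8L) {
  3L * length(MOCK_QUANTILE_PROBS) + 3L * grid * grid * 2L
}

mock_features <- function(img, output_dim, grid = 8L) {
  rgb <- to_rgb(resize_image(img, 224L, 224L)) / 255
  # invariant block: rows = channels, columns = probs; vectorize prob-major
  q <- vapply(1:3, function(c) {
    stats::quantile(rgb[, , c], MOCK_QUANTILE_PROBS, names = FALSE)
  }, numeric(length(MOCK_QUANTILE_PROBS)))
  qblock <- as.vector(t(q))
  # spatial block: channel-major, row-major over the patch grid
  cuts <- round(seq(0, 224, length.out = grid + 1))
  pblock <- numeric(0)
  for (c in 1:3) {
    m <- rgb[, , c]
    for (i in seq_len(grid)) {
      rows <- (cuts[i] + 1):cuts[i + 1]
      for (j in seq_len(grid)) {
        patch <- m[rows, (cuts[j] + 1):cuts[j + 1]]
        pblock <- c(pblock, mean(patch), stats::sd(patch))
      }
    }
  }
  c(qblock, pblock)[seq_len(output_dim)]
}

#' Extract deep-feature vectors from a batch of images
#'
#' Each image is resized to 224 x 224 x 3 and passed through the backbone's
#' feature-extraction portion; rows of the result follow the input order.
#' Extraction is a pure function of (pixels, backbone): repeated calls agree
#' bit-exactly and never depend on batch composition.
#'
#' @param images a list of image matrices/arrays in [0,255].
#' @param backbone a [backbone_spec()]; only `"mock"` runs without the
#'   optional deep-learning toolchain.
#' @return an n x `output_dim` feature matrix with columns `feat1..featD`
#'   and row names taken from `names(images)` when present.
#' @export
extract_features <- function(images, backbone = backbone_spec()) {
  if (backbone$name != "mock") {
    stop(sprintf(paste0(
      "backbone '%s' needs pretrained CNN weights via the optional keras/",
      "tensorflow toolchain, which is not installed; use backbone_spec(\"mock\") ",
      "for a deterministic weight-free extractor"), backbone$name), call. = FALSE)
  }
  rows <- lapply(images, mock_features, output_dim = backbone$output_dim)
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("feat", seq_len(ncol(X)))
  rownames(X) <- names(images)
  X
}
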