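# Image filtering (Gaussian, average, median) and the seven augmentation
# operators used to expand small pest-image datasets.
#
# Images are numeric H x W matrices (grayscale) or H x W x 3 arrays (RGB)
# with intensities in [0, 255]. Every operator preserves shape and clips its
# output back into [0, 255]. Borders are handled by reflective padding so
# filters introduce no dark halos at the edges.

clip_image <- function(img) pmin(pmax(img, 0), 255)

# apply fn(matrix) -> matrix per channel
per_channel <- function(img, fn) {
  if (length(dim(img)) == 3L) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- fn(img[, , c])
    out
  } else {
    fn(img)
  }
}

# reflective index vector for length n padded by r on each side
reflect_index <- function(n, r) {
  idx <- seq.int(1 - r, n + r)
  idx <- ifelse(idx < 1, 2 - idx, idx)
  ifelse(idx > n, 2 * n - idx, idx)
}

check_kernel_size <- function(size) {
  if (size < 1L || size %% 2L == 0L) stop("kernel size must be odd and >= 1")
  as.integer(size)
}

#' Median-filter kernel schedule
#'
#' The feature-extraction loop filters an image with a sequence of growing
#' odd kernels, `a = 2A - 1` for pass index `A = 1, 2, 3, ...`.
#'
#' @param A positive integer pass index (vectorized).
#' @return the odd kernel size(s) `2A - 1`.
#' @export
kernel_size_schedule <- function(A) {
  A <- as.integer(A)
  if (any(A < 1L)) stop("A must be a positive integer")
  2L * A - 1L
}

#' Gaussian kernel from the blur formula
#'
#' Samples `G(x) = 1/(2 pi sigma^2) * exp(-x^2 / (2 sigma^2))` at integer
#' offsets and renormalizes to sum 1.
#'
#' @param sigma positive bandwidth.
#' @param size odd kernel length; defaults to `2 * ceiling(3 sigma) + 1`.
#' @return numeric kernel of length `size` summing to 1, with
#'   `attr(,"unnormalized")` holding the raw `G(x)` samples.
#' @export
gaussian_kernel <- function(sigma, size = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  size <- check_kernel_size(size)
  x <- seq.int(-(size %/% 2), size %/% 2)
  g <- 1 / (2 * pi * sigma^2) * exp(-x^2 / (2 * sigma^2))
  structure(g / sum(g), unnormalized = g)
}

# separable convolution with reflective borders
convolve_separable <- function(mat, kernel) {
  r <- length(kernel) %/% 2
  conv1 <- function(m) {  # along rows (dimension 1)
    n <- nrow(m)
    idx <- reflect_index(n, r)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * m[idx[seq_len(n) + (j - 1L)], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Gaussian blur
#'
#' Separable convolution with the [gaussian_kernel()], reflective borders.
#'
#' @param img H x W matrix or H x W x 3 array in [0,255].
#' @param sigma positive bandwidth.
#' @param size optional odd kernel size.
#' @return the blurred image, same shape, clipped to [0,255].
#' @export
gaussian_filter <- function(img, sigma = 1, size = NULL) {
  k <- gaussian_kernel(sigma, size)
  clip_image(per_channel(img, function(m) convolve_separable(m, as.numeric(k))))
}

#' Average (mean) filter
#'
#' Replaces each pixel by the mean of its `size x size` window, reflective
#' borders.
#'
#' @param img image matrix or array.
#' @param size odd window size.
#' @return the filtered image.
#' @export
average_filter <- function(img, size = 3L) {
  size <- check_kernel_size(size)
  k <- rep(1 / size, size)
  clip_image(per_channel(img, function(m) convolve_separable(m, k)))
}

#' Median filter
#'
#' Replaces each pixel by the median of its `size x size` window, reflective
#' borders. The kernel schedule of the extraction loop is exposed by
#' [kernel_size_schedule()].
#'
#' @param img image matrix or array.
#' @param size odd window size.
#' @return the filtered image.
#' @export
median_filter <- function(img, size = 3L) {
  size <- check_kernel_size(size)
  r <- size %/% 2
  med1 <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    ri <- reflect_index(n1, r); ci <- reflect_index(n2, r)
    stack <- array(NA_real_, c(n1, n2, size * size))
    s <- 0L
    for (dj in seq_len(size)) {
      for (di in seq_len(size)) {
        s <- s + 1L
        stack[, , s] <- m[ri[seq_len(n1) + (di - 1L)],
                          ci[seq_len(n2) + (dj - 1L)]]
      }
    }
    apply(stack, c(1, 2), stats::median)
  }
  clip_image(per_channel(img, med1))
}

#' Apply one image filter by specification
#'
#' @param img image matrix or array.
#' @param kind `"gaussian"`, `"average"` or `"median"`.
#' @param size odd kernel size.
#' @param sigma Gaussian bandwidth (ignored by the other kinds).
#' @return the filtered image.
#' @export
apply_filter <- function(img, kind = c("median", "gaussian", "average"),
                         size = 3L, sigma = 1) {
  kind <- match.arg(kind)
  switch(kind,
         gaussian = gaussian_filter(img, sigma = sigma, size = size),
         average = average_filter(img, size),
         median = median_filter(img, size))
}

AUGMENT_OPS <- c("horizontal_flip", "vertical_flip", "rotation", "shear",
                 "contrast_increase", "reflection", "brightness")

# bilinear sampling of img at (possibly fractional) coordinates; out-of-range
# samples take the fill value
bilinear_sample <- function(m, yy, xx, fill) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  get <- function(y, x) {
    ok <- y >= 1 & y <= h & x >= 1 & x <= w
    v <- rep(fill, length(y))
    v[ok] <- m[cbind(y[ok], x[ok])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

warp_image <- function(img, inverse_map, fill = 0) {
  warp1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    grid <- expand.grid(y = seq_len(h), x = seq_len(w))
    src <- inverse_map(grid$y, grid$x, h, w)
    matrix(bilinear_sample(m, src$y, src$x, fill), h, w)
  }
  per_channel(img, warp1)
}

#' Rotate an image about its center
#'
#' Bilinear resampling; pixels mapped from outside the source take the
#' `fill` value (0 by default). Rotation by 0 degrees is the exact identity.
#'
#' @param img image matrix or array.
#' @param angle rotation angle in degrees (counter-clockwise).
#' @param fill value for out-of-source pixels.
#' @return the rotated image, same shape.
#' @export
rotate_image <- function(img, angle, fill = 0) {
  if (angle %% 360 == 0) return(img)
  th <- angle * pi / 180
  clip_image(warp_image(img, function(y, x, h, w) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    dy <- y - cy; dx <- x - cx
    list(y = cy + cos(th) * dy - sin(th) * dx,
         x = cx + sin(th) * dy + cos(th) * dx)
  }, fill))
}

#' Shear an image horizontally
#'
#' @param img image matrix or array.
#' @param factor shear factor: source column offset per row.
#' @param fill value for out-of-source pixels.
#' @return the sheared image.
#' @export
shear_image <- function(img, factor = 0.1, fill = 0) {
  if (factor == 0) return(img)
  clip_image(warp_image(img, function(y, x, h, w) {
    cy <- (h + 1) / 2
    list(y = y, x = x - factor * (y - cy))
  }, fill))
}

#' Augmentation specification
#'
#' @param operations character vector of operations, a subset of
#'   `"horizontal_flip"`, `"vertical_flip"`, `"rotation"`, `"shear"`,
#'   `"contrast_increase"`, `"reflection"`, `"brightness"` (all seven by
#'   default). `"reflection"` is a vertical-axis mirror and therefore
#'   duplicates `"horizontal_flip"`; both are kept because both appear in
#'   the standard augmentation list this implements.
#' @param angle rotation angle in degrees.
#' @param shear_factor shear factor.
#' @param contrast_factor contrast scale; fixed at 1.2 (a 20% increase) by
#'   default.
#' @param brightness_delta additive brightness shift.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(operations = AUGMENT_OPS, angle = 15,
                         shear_factor = 0.1, contrast_factor = 1.2,
                         brightness_delta = 25) {
  bad <- setdiff(operations, AUGMENT_OPS)
  if (length(bad)) stop("unknown augmentation operation(s): ",
                        paste(bad, collapse = ", "))
  structure(list(operations = operations, angle = angle,
                 shear_factor = shear_factor,
                 contrast_factor = contrast_factor,
                 brightness_delta = brightness_delta),
            class = "augment_spec")
}

flip_horizontal <- function(img) per_channel(img, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
flip_vertical <- function(img) per_channel(img, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])

contrast_scale <- function(img, factor) {
  clip_image(per_channel(img, function(m) mean(m) + factor * (m - mean(m))))
}

#' Generate augmented variants of one image
#'
#' One output per requested operation: flips and reflection are exact pixel
#' permutations; rotation and shear use bilinear resampling with a zero
#' fill; contrast scales deviations from the channel mean by the contrast
#' factor; brightness adds a constant. All outputs are clipped to [0,255].
#'
#' @param img image matrix or array.
#' @param spec an [augment_spec()].
#' @return a named list of augmented images, one per operation, in the
#'   order requested.
#' @export
augment <- function(img, spec = augment_spec()) {
  out <- lapply(spec$operations, function(op) {
    switch(op,
      horizontal_flip = flip_horizontal(img),
      vertical_flip = flip_vertical(img),
      rotation = rotate_image(img, spec$angle),
      shear = shear_image(img, spec$shear_factor),
      contrast_increase = contrast_scale(img, spec$contrast_factor),
      reflection = flip_horizontal(img),
      brightness = clip_image(img + spec$brightness_delta)
    )
  })
  names(out) <- spec$operations
  out
}
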