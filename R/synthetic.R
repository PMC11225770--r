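# Seeded synthetic-data generators: two-class Gaussian feature tables with a
# known informative subset, toy pest/no-pest images, and closed-form
# optimizer benchmark functions. Everything downstream of image collection
# is testable from these alone.

#' Specification of a synthetic two-class feature table
#'
#' @param n_per_class samples per class.
#' @param d total number of features.
#' @param n_informative number of informative features (`<= d`).
#' @param separation class-mean gap on the informative dimensions, in units
#'   of `noise_sd`.
#' @param noise_sd common feature standard deviation.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 200L, d = 50L, n_informative = 10L,
                           separation = 2, noise_sd = 1, seed = 1L) {
  stopifnot(n_informative <= d, separation >= 0, noise_sd > 0,
            n_per_class >= 1, d >= 1)
  structure(list(n_per_class = as.integer(n_per_class), d = as.integer(d),
                 n_informative = as.integer(n_informative),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a two-class Gaussian feature table
#'
#' Class 0 draws every feature from `Normal(0, noise_sd)`. Class 1 draws the
#' `n_informative` informative features from
#' `Normal(separation * noise_sd, noise_sd)` and the rest from the null
#' distribution. The informative index set is returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `X` (2n x d matrix, columns `f1..fd`), `y` (0/1 labels)
#'   and `informative` (the informative column indices).
#' @export
generate_feature_table <- function(spec = synthetic_spec()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_per_class
  X <- matrix(stats::rnorm(2 * n * spec$d, 0, spec$noise_sd), 2 * n, spec$d)
  informative <- seq_len(spec$n_informative)
  cls1 <- (n + 1):(2 * n)
  X[cls1, informative] <- X[cls1, informative] + spec$separation * spec$noise_sd
  colnames(X) <- paste0("f", seq_len(spec$d))
  list(X = X, y = rep(0:1, each = n), informative = informative)
}

# one smooth textured background in [0,255]
toy_background <- function(size) {
  g <- outer(seq_len(size), seq_len(size), function(i, j) {
    140 + 25 * sin(i / 7) * cos(j / 9)
  })
  pmin(pmax(g + matrix(stats::rnorm(size^2, 0, 6), size, size), 0), 255)
}

# stamp a dark filled ellipse; returns list(img, mask)
stamp_blob <- function(img, cy, cx, ry, rx, angle, intensity) {
  size <- nrow(img)
  co <- cos(angle); si <- sin(angle)
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- t(matrix(seq_len(size), size, size)) - cx
  u <- co * yy + si * xx
  v <- -si * yy + co * xx
  mask <- (u / ry)^2 + (v / rx)^2 <= 1
  img[mask] <- intensity
  list(img = img, mask = mask)
}

#' Generate toy pest / no-pest images
#'
#' "Pest" images are a textured background with 1-3 dark elliptical blobs at
#' jittered positions, sizes and orientations; "no-pest" images are the
#' background only. Mean intensity of pest images is therefore lower than of
#' no-pest images, and the blob pixel count per image is returned for
#' construction checks.
#'
#' @param n_per_class images per class.
#' @param size image side length in pixels (`>= 32`).
#' @param seed integer seed.
#' @return list with `images` (list of `size x size` matrices, pest images
#'   first), `labels` (1 = pest, 0 = no pest) and `blob_pixels` (integer
#'   count of blob pixels per image).
#' @export
generate_toy_images <- function(n_per_class = 20L, size = 64L, seed = 1L) {
  if (size < 32L) stop("size must be at least 32")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  images <- vector("list", 2L * n_per_class)
  blob_pixels <- integer(2L * n_per_class)
  for (i in seq_len(2L * n_per_class)) {
    img <- toy_background(size)
    pest <- i <= n_per_class
    if (pest) {
      n_blob <- sample(1:3, 1L)
      total_mask <- matrix(FALSE, size, size)
      for (b in seq_len(n_blob)) {
        # radii are bounded well above the noise floor so every pest image
        # carries a clearly separable dark-pixel mass
        st <- stamp_blob(img,
                         cy = stats::runif(1, size * 0.2, size * 0.8),
                         cx = stats::runif(1, size * 0.2, size * 0.8),
                         ry = stats::runif(1, size * 0.09, size * 0.16),
                         rx = stats::runif(1, size * 0.05, size * 0.11),
                         angle = stats::runif(1, 0, pi),
                         intensity = stats::runif(1, 25, 55))
        img <- st$img
        total_mask <- total_mask | st$mask
      }
      blob_pixels[i] <- sum(total_mask)
    }
    images[[i]] <- img
  }
  list(images = images,
       labels = rep(1:0, each = n_per_class),
       blob_pixels = blob_pixels)
}

#' Closed-form optimizer benchmark functions
#'
#' @param name `"sphere"`, `"rastrigin"` or `"rosenbrock"`.
#' @param dim problem dimension.
#' @return list with `fn` (the objective), `lower`, `upper` (bound vectors),
#'   `optimum_position` and `optimum_value`.
#' @export
benchmark_function <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                               dim = 5L) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      lower = rep(-5, dim), upper = rep(5, dim),
      optimum_position = rep(0, dim), optimum_value = 0
    ),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      lower = rep(-5.12, dim), upper = rep(5.12, dim),
      optimum_position = rep(0, dim), optimum_value = 0
    ),
    rosenbrock = list(
      fn = function(x) {
        if (length(x) == 1L) return((1 - x)^2)
        sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
      },
      lower = rep(-5, dim), upper = rep(10, dim),
      optimum_position = rep(1, dim), optimum_value = 0
    )
  )
}
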