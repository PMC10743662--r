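new_labeled_image_set <- function(pixels, labels, classes, image_size,
                                  bit_depth) {
  structure(list(pixels = pixels, labels = labels, classes = classes,
                 image_size = as.integer(image_size),
                 bit_depth = as.integer(bit_depth)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  n <- table(factor(x$labels$split, c("train", "validate", "test")))
  cat(sprintf("<labeled_image_set> %d images (%dx%d, %d-bit), %d classes\n",
              ncol(x$pixels), x$image_size, x$image_size, x$bit_depth,
              length(x$classes)))
  cat(sprintf("  splits: train %d / validate %d / test %d\n",
              n["train"], n["validate"], n["test"]))
  invisible(x)
}

#' Configuration for the synthetic band-signal generator
#'
#' Describes 12-bit grayscale images in which each class's evidence is a
#' soft-edged blob whose intensities sit inside a narrow, class-specific
#' intensity band, on top of a smooth background field spanning the full
#' representable range plus Gaussian noise. Because the within-band
#' lesion contrast is small relative to the full range, the signal is
#' nearly invisible after coarse quantization or under the wrong window,
#' while windowing to the class's band makes it high-contrast - the
#' mechanism that makes windowing worth learning.
#'
#' @param n_train,n_validate,n_test Images per split.
#' @param image_size Square image side in pixels (default 224).
#' @param bit_depth Bit depth of generated pixel values (default 12).
#' @param n_classes Number of finding classes (default 14; class names
#'   are taken from [chexpert_classes()] when `n_classes` is 14,
#'   otherwise `class01`, `class02`, ...).
#' @param bands Data frame with columns `level`, `width`: the intensity
#'   band carrying each class's lesion. Defaults to `n_classes` bands of
#'   width 400 with levels evenly spread over `[250, 3800]`, so each
#'   class has a distinct recoverable window target.
#' @param lesion_contrast Peak-to-trough intensity modulation of a lesion
#'   blob (default 200). Must be smaller than every band width.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise in
#'   intensity units (default 60).
#' @param prevalence Per-class probability that an image is positive
#'   (scalar or length `n_classes`; default 0.3).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_train = 2000, n_validate = 400, n_test = 400,
                             image_size = 224, bit_depth = 12,
                             n_classes = 14, bands = NULL,
                             lesion_contrast = 200, noise_sd = 60,
                             prevalence = 0.3, seed = 1) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      level = round(seq(250, 3800, length.out = n_classes)),
      width = 400
    )
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(nrow(bands) == n_classes)
  lim <- window_limits(bands)
  if (any(lim$lower < 0) || any(lim$upper >= 2^bit_depth)) {
    rlang::abort("Every class band must lie within the representable range.",
                 class = "radwindow_error_invalid_config")
  }
  if (any(lesion_contrast >= bands$width)) {
    rlang::abort("`lesion_contrast` must be smaller than every band width.",
                 class = "radwindow_error_invalid_config")
  }
  prevalence <- rep_len(prevalence, n_classes)
  classes <- if (n_classes == 14) chexpert_classes() else
    sprintf("class%02d", seq_len(n_classes))
  structure(list(n_train = n_train, n_validate = n_validate, n_test = n_test,
                 image_size = image_size, bit_depth = bit_depth,
                 n_classes = n_classes, bands = bands, classes = classes,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "synthetic_config")
}

# one background field: a few random low-frequency cosine modes,
# histogram-equalized (rank-mapped) onto the full representable range, so
# every image's background has the same, uniform intensity distribution -
# the analogue of histogram-standardized acquisition
synth_background <- function(size, bit_depth) {
  xs <- seq(0, 1, length.out = size)
  g <- expand.grid(x = xs, y = xs)
  f <- rep(0, size * size)
  for (i in 1:3) {
    fx <- stats::runif(1, 1, 3)
    fy <- stats::runif(1, 1, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.5, 1) *
      cos(2 * pi * (fx * g$x + fy * g$y) + ph)
  }
  (rank(f, ties.method = "first") - 1) / (size * size - 1) * (2^bit_depth - 1)
}

# unit-peak Gaussian bump at a random center/scale
synth_blob_mask <- function(size) {
  cx <- stats::runif(1, 0.2, 0.8) * size
  cy <- stats::runif(1, 0.2, 0.8) * size
  sd <- stats::runif(1, 0.12, 0.25) * size
  d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
  exp(-as.numeric(d2) / (2 * sd^2))
}

#' Generate a synthetic band-signal image set
#'
#' Draws per-class labels at the configured prevalence and renders each
#' image as an equalized background field plus noise, with one
#' sharp-edged plateau blob per positive class: interior intensities
#' `level_k + contrast * (G' - 1/2)` (`G'` the blob's plateau profile,
#' ~1 over the blob core), so a lesion occupies the upper half of its
#' class band, with a thin transition rim where it blends into the
#' background. Pixels are clipped to the representable range and
#' rounded to integers. Deterministic given the config (including its
#' seed).
#'
#' @param cfg A [synthetic_config()].
#' @return A `labeled_image_set`: list with `pixels` (a pixels x images
#'   numeric matrix, column-major images), `labels` (tibble: `image_id`,
#'   `split`, one 0/1 column per class), `classes`, `image_size`,
#'   `bit_depth`. Use [write_image_set()] to materialize it as 16-bit
#'   images plus a `labels.csv`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_train + cfg$n_validate + cfg$n_test
    split <- rep(c("train", "validate", "test"),
                 c(cfg$n_train, cfg$n_validate, cfg$n_test))
    size <- cfg$image_size
    p <- size * size
    maxval <- 2^cfg$bit_depth - 1
    Y <- matrix(0L, n, cfg$n_classes)
    X <- matrix(0, p, n)
    for (i in seq_len(n)) {
      y <- as.integer(stats::runif(cfg$n_classes) < cfg$prevalence)
      Y[i, ] <- y
      px <- synth_background(size, cfg$bit_depth)
      for (k in which(y == 1L)) {
        g <- synth_blob_mask(size)
        core <- pmin(g / 0.6, 1)
        m <- stats::plogis((g - 0.35) / 0.03)
        target <- cfg$bands$level[k] + cfg$lesion_contrast * (core - 0.5)
        px <- (1 - m) * px + m * target
      }
      px <- px + stats::rnorm(p, sd = cfg$noise_sd)
      X[, i] <- round(pmin(pmax(px, 0), maxval))
    }
    colnames(Y) <- cfg$classes
    labels <- tibble::tibble(
      image_id = sprintf("img%05d", seq_len(n)),
      split = split
    )
    labels <- dplyr::bind_cols(labels, tibble::as_tibble(Y))
    new_labeled_image_set(X, labels, cfg$classes, size, cfg$bit_depth)
  })
}

# pixels (p x m matrix) and 0/1/-1/NA label matrix (m x C) for one split
split_matrices <- function(data, split) {
  idx <- which(data$labels$split == split)
  if (!length(idx)) {
    rlang::abort(paste0("Split has no images: ", split),
                 class = "radwindow_error_empty_split")
  }
  Y <- as.matrix(data$labels[idx, data$classes, drop = FALSE])
  storage.mode(Y) <- "double"
  list(X = data$pixels[, idx, drop = FALSE], Y = Y, idx = idx)
}
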