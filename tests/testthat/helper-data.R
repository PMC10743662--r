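# small fixtures built in code

tiny_config <- function(n_train = 60, n_validate = 30, n_test = 30,
                        image_size = 16, n_classes = 3, seed = 101,
                        bands = NULL, ...) {
  if (is.null(bands)) {
    bands <- tibble::tibble(level = seq(600, 3400, length.out = n_classes),
                            width = 400)
  }
  synthetic_config(
    n_train = n_train, n_validate = n_validate, n_test = n_test,
    image_size = image_size, n_classes = n_classes, bands = bands,
    seed = seed, ...
  )
}

random_12bit_image <- function(size = 16, seed = 1) {
  withr::with_seed(seed, matrix(sample(0:4095, size * size, replace = TRUE),
                                size, size))
}

# brute-force scalar windowing: per-pixel loop, the independent oracle
oracle_window <- function(pixels, level, width) {
  L <- level - width / 2
  U <- level + width / 2
  out <- pixels
  for (i in seq_along(out)) {
    v <- out[i]
    if (v < L) v <- L
    if (v > U) v <- U
    out[i] <- v
  }
  out
}

# O(n^2) pairwise AUC with half-credit ties, the independent oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
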