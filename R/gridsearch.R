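#' Enumerate the fixed-window grid
#'
#' The single-window search space: a level of 100 plus levels from 250
#' to 3500 in steps of 250 (15 levels), each combined with widths 500,
#' 1000, 1500, 2000 and 3000 - 75 windows in level-major order. The
#' full-range window (2048, 4096) is not part of the grid; it is the
#' no-windowing reference the grid is compared against.
#'
#' @return A [window_set()] of 75 rows.
#' @export
enumerate_grid <- function() {
  levels <- c(100, seq(250, 3500, by = 250))
  widths <- c(500, 1000, 1500, 2000, 3000)
  g <- tidyr::expand_grid(level = levels, width = widths)
  window_set(g$level, g$width)
}

#' Desk-scale fixed-window grid search with a linear probe
#'
#' Scores every candidate window by how separable each class becomes
#' after windowing: images are windowed and rescaled to `[0, 255]`, each
#' image is summarized by block-wise gray-tone histograms (counts of
#' pixels per intensity bin in each cell of a `pool` x `pool` spatial
#' grid), and a ridge-regularized linear probe per class is fit on those
#' features on the train split and evaluated by AUC on the validation
#' and test splits. This is a fast stand-in for retraining a full
#' classifier per window; it preserves the ranking signal the
#' window-selection step needs. Applying the identical feature map and
#' probe to differently windowed (or bit-reduced) versions of the same
#' images isolates the effect of the intensity transform.
#'
#' @param data A `labeled_image_set`.
#' @param windows Candidate windows (default [enumerate_grid()]).
#' @param pool Spatial grid of the histogram features (default 4).
#' @param bin_edges Intensity bin edges on the 0-255 windowed scale
#'   (default `c(0, 32, 96, 160, 224, 256)`: two saturation-side bins
#'   and three interior tone bins).
#' @param ridge Ridge penalty of the probe (default 1).
#' @return A tibble of class `grid_result` in long form: `level`,
#'   `width`, `class`, `val_auc`, `test_auc`.
#' @export
grid_search_probe <- function(data, windows = enumerate_grid(), pool = 4,
                              bin_edges = c(0, 32, 96, 160, 224, 256),
                              ridge = 1) {
  stopifnot(inherits(data, "labeled_image_set"))
  windows <- as_window_set(windows)
  check_positive_width(windows)
  tr <- split_matrices(data, "train")
  va <- split_matrices(data, "validate")
  te <- split_matrices(data, "test")
  size <- data$image_size
  block <- size %/% pool
  stopifnot(size %% pool == 0)
  rowb <- rep(rep(seq_len(pool), each = block), times = size)
  colb <- rep(seq_len(pool), each = block * size)
  block_id <- (colb - 1) * pool + rowb
  B <- length(bin_edges) - 1
  feat <- function(X, aff) {
    W <- apply_affine_window(X, aff)
    bin <- matrix(findInterval(W, bin_edges, rightmost.closed = TRUE),
                  nrow(X), ncol(X))
    F <- matrix(0, pool * pool * B, ncol(X))
    for (b in seq_len(B)) {
      F[seq(b, by = B, length.out = pool * pool), ] <-
        rowsum((bin == b) * 1, block_id)
    }
    F / (block * block)
  }
  res <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    aff <- window_to_affine(windows[i, ], 255)
    Ftr <- feat(tr$X, aff)
    ctr <- rowMeans(Ftr)
    Ftr <- Ftr - ctr
    Fva <- feat(va$X, aff) - ctr
    Fte <- feat(te$X, aff) - ctr
    G <- Ftr %*% t(Ftr) + ridge * diag(nrow(Ftr))
    purrr::map_dfr(seq_along(data$classes), function(k) {
      y <- tr$Y[, k]
      keep <- !is.na(y) & y %in% c(0, 1)
      w <- solve(G, Ftr[, keep, drop = FALSE] %*% (y[keep] - mean(y[keep])))
      score <- function(F, Y) {
        kp <- !is.na(Y[, k]) & Y[, k] %in% c(0, 1)
        auc(as.numeric(crossprod(F[, kp, drop = FALSE], w)), Y[kp, k],
            na_undefined = TRUE)
      }
      tibble::tibble(level = windows$level[i], width = windows$width[i],
                     class = data$classes[k],
                     val_auc = score(Fva, va$Y),
                     test_auc = score(Fte, te$Y))
    })
  })
  class(res) <- c("grid_result", class(res))
  res
}

#' Select the multi-window initialization set from grid results
#'
#' Takes, for every class, the `k_per_class` windows with the highest
#' validation AUC, forms the union over classes, appends the full-range
#' window (2048, 4096) and deduplicates. Ties in validation AUC are
#' broken deterministically by smaller width, then smaller level. The
#' result is the window set used to initialize the trainable
#' multi-window layer.
#'
#' @param results A long tibble with columns `level`, `width`, `class`
#'   and `val_auc` (e.g. from [grid_search_probe()]).
#' @param k_per_class Windows kept per class (default 3).
#' @return A [window_set()]; windows ordered by level then width, with
#'   the full-range window last.
#' @export
select_init_windows <- function(results, k_per_class = 3) {
  needed <- c("level", "width", "class", "val_auc")
  if (!all(needed %in% names(results))) {
    rlang::abort(paste0("`results` must have columns: ",
                        paste(needed, collapse = ", ")),
                 class = "radwindow_error_invalid_grid")
  }
  if (anyNA(results$val_auc)) {
    rlang::abort("Missing validation AUCs in grid results.",
                 class = "radwindow_error_invalid_grid")
  }
  top <- results |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(.data$val_auc), .data$width, .data$level,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k_per_class) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$level, .data$width) |>
    dplyr::arrange(.data$level, .data$width)
  full <- full_range_window()
  top <- dplyr::filter(top, !(.data$level == full$level &
                                .data$width == full$width))
  out <- dplyr::bind_rows(top, tibble::tibble(level = full$level,
                                              width = full$width))
  window_set(out$level, out$width)
}

#' Export grid-search results as CSV
#'
#' Writes one row per window with per-class validation/test AUC columns
#' and their means - the machine-readable twin of a fixed-window
#' results table.
#'
#' @param results Long grid results (see [grid_search_probe()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_results <- function(results, path) {
  wide <- results |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("val_auc", "test_auc")) |>
    dplyr::mutate(
      mean_val_auc = rowMeans(dplyr::pick(dplyr::starts_with("val_auc_")),
                              na.rm = TRUE),
      mean_test_auc = rowMeans(dplyr::pick(dplyr::starts_with("test_auc_")),
                               na.rm = TRUE))
  readr::write_csv(wide, path)
  invisible(path)
}
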