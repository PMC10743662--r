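#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative,
#' with ties counted 1/2. Computed from midranks, so it is exact and
#' invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length.
#' @param na_undefined If `TRUE`, return `NA` when only one class is
#'   present instead of erroring.
#' @return AUC in `[0, 1]`, or `NA` for single-class labels when
#'   `na_undefined = TRUE`.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1
#' @export
auc <- function(scores, labels, na_undefined = FALSE) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    if (na_undefined) return(NA_real_)
    rlang::abort("AUC is undefined: labels contain a single class.",
                 class = "radwindow_error_undefined_auc")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class AUCs with image-level bootstrap confidence intervals
#'
#' Point estimates are per-class AUCs over the supplied images; 95%
#' confidence intervals come from a nonparametric bootstrap that
#' resamples whole images (rows) with replacement `n_resamples` times
#' (default 10,000) and takes the 2.5th and 97.5th percentiles of the
#' resampled AUCs per class. All classes share each resample's image
#' indices - resampling is at the image level, never per class. A class
#' whose resample contains a single outcome is skipped in that resample
#' (not redrawn); `n_defined` reports how many resamples were usable
#' per class.
#'
#' @param scores Numeric matrix or data frame, images x classes, of
#'   predicted scores.
#' @param labels Matching matrix/data frame of labels (1 positive, 0
#'   negative; -1 and `NA` cells are excluded classwise).
#' @param n_resamples Bootstrap resamples (default 10000).
#' @param seed Integer seed making the report reproducible.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `eval_report`: a tibble with columns
#'   `class`, `auc`, `ci_low`, `ci_high`, `n_defined`, carrying
#'   `mean_auc`, `n_images`, `n_resamples`, `conf` and `seed` as
#'   attributes. `mean_auc` is the arithmetic mean of the defined
#'   per-class AUCs.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_resamples = 10000,
                             seed = 1, conf = 0.95) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  C <- ncol(scores)
  n <- nrow(scores)
  cls <- colnames(scores)
  if (is.null(cls)) cls <- sprintf("class%02d", seq_len(C))
  usable <- !is.na(labels) & labels %in% c(0, 1)
  point <- vapply(seq_len(C), function(k) {
    keep <- usable[, k]
    if (!any(keep)) return(NA_real_)
    auc(scores[keep, k], labels[keep, k], na_undefined = TRUE)
  }, numeric(1))
  boots <- matrix(NA_real_, n_resamples, C)
  withr::with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      for (k in seq_len(C)) {
        keep <- usable[idx, k]
        if (!any(keep)) next
        boots[b, k] <- auc(scores[idx, k][keep], labels[idx, k][keep],
                           na_undefined = TRUE)
      }
    }
  })
  alpha <- (1 - conf) / 2
  ci <- t(apply(boots, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7)
  }))
  out <- tibble::tibble(class = cls, auc = point,
                        ci_low = ci[, 1], ci_high = ci[, 2],
                        n_defined = colSums(!is.na(boots)))
  attr(out, "mean_auc") <- mean(point, na.rm = TRUE)
  attr(out, "n_images") <- n
  attr(out, "n_resamples") <- n_resamples
  attr(out, "conf") <- conf
  attr(out, "seed") <- seed
  class(out) <- c("eval_report", class(out))
  out
}

#' Evaluate a trained model on one split
#'
#' Scores the split with [predict_scores()] and summarizes per-class
#' AUCs and bootstrap confidence intervals with [bootstrap_auc_ci()].
#'
#' @param object A `window_fit` or `radwindow_model`.
#' @param data A `labeled_image_set`.
#' @param split Split to evaluate (default `"test"`).
#' @param n_resamples,seed,conf Passed to [bootstrap_auc_ci()].
#' @return An `eval_report`.
#' @export
evaluate_model <- function(object, data, split = "test",
                           n_resamples = 10000, seed = 1, conf = 0.95) {
  sc <- predict_scores(object, data, split)
  sm <- split_matrices(data, split)
  bootstrap_auc_ci(as.matrix(sc[, data$classes]), sm$Y,
                   n_resamples = n_resamples, seed = seed, conf = conf)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classes, mean AUC %.3f (%d images, %d bootstrap resamples)\n",
              nrow(x), attr(x, "mean_auc"), attr(x, "n_images"),
              attr(x, "n_resamples")))
  NextMethod()
}

#' Export an evaluation report as CSV
#'
#' Writes the `class, auc, ci_low, ci_high` table (the machine-readable
#' form of a per-class AUC results table).
#'
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(report), "class", "auc",
                                 "ci_low", "ci_high"), path)
  invisible(path)
}
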