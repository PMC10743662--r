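#' Construct a set of intensity windows
#'
#' A window is the classic radiological display transform: a pair
#' (level, width) in raw intensity units. The window level `WL` is the
#' center of the displayed intensity range and the window width `WW` its
#' extent, so the window spans `[WL - WW/2, WL + WW/2]`. Narrower windows
#' spend the output gray scale on a smaller intensity range and therefore
#' raise contrast inside it.
#'
#' @param level Numeric vector of window levels (centers), intensity units.
#' @param width Numeric vector of window widths, intensity units. Must be
#'   strictly positive unless `allow_inverted = TRUE` (used internally when
#'   reporting windows recovered from negative learned weights).
#' @param allow_inverted Permit negative widths, flagging them in an
#'   `inverted` column instead of erroring.
#'
#' @return A tibble of class `window_set` with columns `level`, `width`
#'   (and `inverted` when `allow_inverted = TRUE`).
#' @examples
#' window_set(level = c(2048, 1250), width = c(4096, 1000))
#' @export
window_set <- function(level, width, allow_inverted = FALSE) {
  if (length(level) != length(width)) {
    rlang::abort("`level` and `width` must have the same length.",
                 class = "radwindow_error_invalid_window")
  }
  level <- as.numeric(level)
  width <- as.numeric(width)
  if (anyNA(level) || anyNA(width)) {
    rlang::abort("Window levels and widths must be non-missing.",
                 class = "radwindow_error_invalid_window")
  }
  if (!allow_inverted && any(width <= 0)) {
    rlang::abort("Window widths must be strictly positive.",
                 class = "radwindow_error_invalid_window")
  }
  out <- tibble::tibble(level = level, width = width)
  if (allow_inverted) out$inverted <- width < 0
  class(out) <- c("window_set", class(out))
  out
}

#' The full-range identity window
#'
#' For `bit_depth = 12` this is level 2048, width 4096: the window whose
#' limits are exactly the representable range, so applying it leaves a
#' 12-bit image unchanged.
#'
#' @param bit_depth Integer bit depth of the data the window should span.
#' @return A one-row [window_set()].
#' @export
full_range_window <- function(bit_depth = 12) {
  window_set(level = 2^bit_depth / 2, width = 2^bit_depth)
}

as_window_set <- function(windows) {
  if (!is.data.frame(windows) || !all(c("level", "width") %in% names(windows))) {
    rlang::abort("`windows` must be a data frame with columns `level` and `width`.",
                 class = "radwindow_error_invalid_window")
  }
  windows
}

check_positive_width <- function(windows) {
  if (any(!is.finite(windows$width)) || any(windows$width <= 0)) {
    rlang::abort("Window widths must be strictly positive.",
                 class = "radwindow_error_invalid_window")
  }
  invisible(windows)
}

#' Window display limits
#'
#' Converts (level, width) pairs to the lower and upper limits of the
#' displayed intensity range: `lower = level - width/2` and
#' `upper = level + width/2`. Pixels below `lower` saturate to black,
#' pixels above `upper` to white. For example, a CT lung window with level
#' -600 HU and width 1500 HU displays everything below -1350 HU as black
#' and everything above 150 HU as white.
#'
#' @param windows A data frame with columns `level` and `width` (e.g. a
#'   [window_set()]).
#' @return The input tibble with `lower` and `upper` columns added.
#' @examples
#' window_limits(window_set(-600, 1500))
#' @export
window_limits <- function(windows) {
  windows <- as_window_set(windows)
  check_positive_width(windows)
  dplyr::mutate(tibble::as_tibble(windows),
                lower = .data$level - .data$width / 2,
                upper = .data$level + .data$width / 2)
}

#' Apply a window to pixel intensities
#'
#' Elementwise clamp of pixel values to the window's limits:
#' `min(max(px, L), U)` with `L = level - width/2`, `U = level + width/2`.
#' Values strictly inside `(L, U)` are unchanged; the operation is
#' monotone and idempotent.
#'
#' @param pixels Numeric vector, matrix or array of finite intensities.
#' @param windows A one-row window data frame (level, width).
#' @return Object of the same shape as `pixels`, clamped to `[L, U]`.
#' @examples
#' apply_window(c(-2000, 0, 100, 4095), window_set(-600, 1500))
#' @export
apply_window <- function(pixels, windows) {
  windows <- as_window_set(windows)
  if (nrow(windows) != 1L) {
    rlang::abort("`apply_window()` expects a single window (one row).",
                 class = "radwindow_error_invalid_window")
  }
  check_positive_width(windows)
  lim <- window_limits(windows)
  out <- pmin(pmax(pixels, lim$lower), lim$upper)
  out
}

#' Clamped-affine equivalent of a window
#'
#' Rewrites windows as the parameters of a clamped affine map (a 1x1
#' convolution with output clamping): `px -> clamp(weight * px + bias, 0,
#' out_max)` with `weight = out_max / width` and
#' `bias = -(out_max / width) * (level - width / 2)`. The map sends the
#' window's lower limit to 0 and its upper limit to `out_max`, and is the
#' initialization used for each channel of the trainable window layer.
#'
#' @param windows Data frame of windows (level, width), widths > 0.
#' @param out_max Upper bound of the output intensity scale (default 255,
#'   the conventional 8-bit display scale).
#' @return Tibble of class `affine_window_params` with columns `weight`,
#'   `bias`, `out_max`.
#' @examples
#' window_to_affine(window_set(1250, 1000))
#' @export
window_to_affine <- function(windows, out_max = 255) {
  windows <- as_window_set(windows)
  check_positive_width(windows)
  if (!is.numeric(out_max) || length(out_max) != 1L || out_max <= 0) {
    rlang::abort("`out_max` must be a single positive number.",
                 class = "radwindow_error_invalid_parameter")
  }
  w <- out_max / windows$width
  out <- tibble::tibble(
    weight = w,
    bias = -w * (windows$level - windows$width / 2),
    out_max = out_max
  )
  class(out) <- c("affine_window_params", class(out))
  out
}

#' Recover windows from clamped-affine parameters
#'
#' Inverts [window_to_affine()]: `width = out_max / weight` and
#' `level = -bias / weight + width / 2`. This is how window settings are
#' read back out of a trained window layer. A negative weight yields a
#' negative width; such windows are reported with `inverted = TRUE`
#' rather than erroring, so that learned layers can always be summarised.
#' A zero weight carries no window information and is an error (callers
#' that must stay total, like [extract_learned_windows()], flag such
#' channels as degenerate instead).
#'
#' @param params Data frame with columns `weight`, `bias` and optionally
#'   `out_max` (default 255).
#' @return A [window_set()] tibble with an `inverted` column.
#' @examples
#' affine_to_window(window_to_affine(window_set(2500, 3000)))
#' @export
affine_to_window <- function(params) {
  if (!is.data.frame(params) || !all(c("weight", "bias") %in% names(params))) {
    rlang::abort("`params` must have columns `weight` and `bias`.",
                 class = "radwindow_error_invalid_parameter")
  }
  out_max <- if ("out_max" %in% names(params)) params$out_max else 255
  if (any(params$weight == 0)) {
    rlang::abort("Zero weight: window is not recoverable.",
                 class = "radwindow_error_nonrecoverable_window")
  }
  width <- out_max / params$weight
  level <- -params$bias / params$weight + width / 2
  window_set(level = level, width = width, allow_inverted = TRUE)
}

#' Apply a clamped affine window map
#'
#' Computes `clamp(weight * px + bias, 0, out_max)` elementwise. For
#' parameters produced by [window_to_affine()] this equals the plain
#' window operator followed by the affine rescale of `[L, U]` onto
#' `[0, out_max]`.
#'
#' @param pixels Numeric vector, matrix or array of finite intensities.
#' @param params One-row data frame with `weight`, `bias` and optionally
#'   `out_max`.
#' @return Same shape as `pixels`, values in `[0, out_max]`.
#' @export
apply_affine_window <- function(pixels, params) {
  if (!is.data.frame(params) || nrow(params) != 1L) {
    rlang::abort("`params` must be a one-row data frame.",
                 class = "radwindow_error_invalid_parameter")
  }
  out_max <- if ("out_max" %in% names(params)) params$out_max else 255
  pmin(pmax(params$weight * pixels + params$bias, 0), out_max)
}

#' Read or write a window set
#'
#' Window sets are serialized as a list of `{level, width}` records in
#' YAML or JSON. The loader validates that every width is strictly
#' positive.
#'
#' @param path File path; format is inferred from the extension
#'   (`.yaml`/`.yml` or `.json`) unless `format` is given.
#' @param format `"yaml"` or `"json"`.
#' @return `read_windows()` returns a [window_set()]; `write_windows()`
#'   returns `path` invisibly.
#' @export
read_windows <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  recs <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble))
  }
  recs <- tibble::as_tibble(recs)
  if (!all(c("level", "width") %in% names(recs))) {
    rlang::abort("Window file must contain `level` and `width` fields.",
                 class = "radwindow_error_invalid_window")
  }
  window_set(recs$level, recs$width)
}

#' @rdname read_windows
#' @param windows A window data frame to serialize.
#' @export
write_windows <- function(windows, path, format = c("auto", "yaml", "json")) {
  windows <- as_window_set(windows)
  check_positive_width(windows)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  recs <- purrr::map2(windows$level, windows$width,
                      function(l, w) list(level = l, width = w))
  if (format == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}
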