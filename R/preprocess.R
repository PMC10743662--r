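#' ImageNet per-channel normalization constants
#'
#' Conventional mean and standard deviation (on the 0-1 scale) used to
#' normalize inputs to ImageNet-pretrained backbones.
#'
#' @return A list with numeric vectors `mean` and `std`, length 3.
#' @export
imagenet_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), std = c(0.229, 0.224, 0.225))
}

new_raw_image <- function(pixels, bit_depth, source_id = "") {
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 source_id = source_id),
            class = "raw_image")
}

#' Construct a raw grayscale image
#'
#' Wraps a 2-D nonnegative integer intensity matrix together with its
#' declared bit depth. All pixels must be representable at that depth.
#'
#' @param pixels 2-D numeric matrix of nonnegative integer intensities.
#' @param bit_depth One of 8, 12, 16.
#' @param source_id Opaque identifier (e.g. the file the image came from).
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, bit_depth = 12, source_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    rlang::abort("`pixels` must be a nonempty 2-D matrix.",
                 class = "radwindow_error_invalid_image")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    rlang::abort("`bit_depth` must be 8, 12 or 16.",
                 class = "radwindow_error_invalid_image")
  }
  if (any(pixels < 0) || any(pixels != floor(pixels))) {
    rlang::abort("Pixels must be nonnegative integers.",
                 class = "radwindow_error_invalid_image")
  }
  if (any(pixels >= 2^bit_depth)) {
    rlang::abort(
      sprintf("Pixel value %d exceeds declared %d-bit depth.",
              max(pixels), bit_depth),
      class = "radwindow_error_depth_mismatch")
  }
  new_raw_image(pixels, bit_depth, source_id)
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %dx%d, %d-bit, max %d%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, max(x$pixels),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

png_stored_bit_depth <- function(path) {
  # PNG IHDR: bit depth is the byte at offset 24 (0-based) of the file
  hdr <- readBin(path, "raw", n = 25L)
  as.integer(hdr[25L])
}

#' Load a grayscale radiograph
#'
#' Reads an 8/16-bit grayscale PNG or TIFF and verifies that the observed
#' intensities fit the declared bit depth (12-bit radiographs are
#' conventionally stored in 16-bit containers). DICOM input is not
#' supported by this implementation; export pixel data to 16-bit
#' PNG/TIFF first. No photometric inversion or rescale slope/intercept
#' handling is applied: stored values are taken as-is.
#'
#' @param path Path to a grayscale PNG or TIFF file.
#' @param expected_bit_depth Declared bit depth of the pixel values
#'   (default 12). Any pixel at or above `2^expected_bit_depth` raises a
#'   depth-mismatch error.
#' @return A [raw_image()].
#' @export
load_image <- function(path, expected_bit_depth = 12) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "radwindow_error_io")
  }
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else {
    v <- png::readPNG(path)
    stored <- png_stored_bit_depth(path)
    px <- round(v * (2^stored - 1))
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1 &&
        !all(abs(px[, , 1] - px[, , max(dim(px)[3], 1)]) < 1e-9)) {
      rlang::abort("Expected a grayscale image.",
                   class = "radwindow_error_io")
    }
    px <- px[, , 1]
  }
  px <- matrix(as.numeric(px), nrow = dim(px)[1])
  if (any(px >= 2^expected_bit_depth)) {
    rlang::abort(
      sprintf("Observed maximum %d exceeds declared %d-bit depth.",
              max(px), expected_bit_depth),
      class = "radwindow_error_depth_mismatch")
  }
  raw_image(px, bit_depth = expected_bit_depth, source_id = basename(path))
}

#' Write a raw image to a 16-bit TIFF
#'
#' Lossless storage for 12-bit pixel data (the PNG writer available to
#' this package is 8-bit only, so high-bit-depth images go to TIFF).
#'
#' @param img A [raw_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raw_image"))
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Reduce the bit depth of an image
#'
#' Maps pixels by `floor(px * (2^target - 1) / (2^source - 1))`: a global
#' linear rescale of the representable range, emulating the dataset-wide
#' compression applied when high-bit-depth collections are released at
#' 8-bit. It is monotone, maps 0 to 0 and the source maximum to the
#' target maximum, and collapses `2^(source-target)` adjacent gray values
#' onto each output value, which is what hides low-contrast structure.
#'
#' @param img A [raw_image()].
#' @param target_bits Target depth, at most the image's current depth.
#' @return A [raw_image()] at the target depth.
#' @examples
#' img <- raw_image(matrix(c(0L, 4095L), 1), bit_depth = 12)
#' reduce_bit_depth(img, 8)$pixels
#' @export
reduce_bit_depth <- function(img, target_bits) {
  stopifnot(inherits(img, "raw_image"))
  if (target_bits > img$bit_depth) {
    rlang::abort("Cannot increase bit depth.",
                 class = "radwindow_error_invalid_reduction")
  }
  scale <- (2^target_bits - 1) / (2^img$bit_depth - 1)
  px <- floor(img$pixels * scale)
  new_raw_image(px, as.integer(target_bits), img$source_id)
}

resize_bilinear <- function(px, out_size) {
  if (nrow(px) == out_size && ncol(px) == out_size) return(px)
  out <- EBImage::resize(EBImage::Image(px), w = out_size, h = out_size,
                         filter = "bilinear", antialias = TRUE)
  EBImage::imageData(out)
}

#' Fixed-window preprocessing to a model input
#'
#' The deterministic preprocessing path: apply a window (clamp to the
#' window's `[L, U]`), rescale that range affinely onto `[0, 255]`,
#' resize to `out_size` x `out_size` with bilinear interpolation,
#' replicate to three channels and normalize by the ImageNet per-channel
#' mean and standard deviation. `windows = NULL` means no windowing,
#' i.e. the full-range window for the image's bit depth (level 2048,
#' width 4096 for 12-bit data), under which the rescale is the plain
#' division by the representable range.
#'
#' The `[L, U] -> [0, 255]` rescale is per window, not per image, so a
#' constant image maps to a well-defined gray (the window level maps to
#' 127.5) and the fixed path agrees exactly with the clamped-affine math
#' of the trainable window layer.
#'
#' @param img A [raw_image()].
#' @param windows A one-row window data frame, or `NULL` for the
#'   full-range window.
#' @param out_size Output spatial size (default 224).
#' @param normalize Apply ImageNet normalization (default `TRUE`; when
#'   `FALSE` the returned pixels are on the 0-255 scale).
#' @return An object of class `model_input`: list with `pixels` (an
#'   `out_size` x `out_size` x 3 array) and `normalization` (the
#'   mean/std record applied, or `NULL`).
#' @export
preprocess_fixed <- function(img, windows = NULL, out_size = 224,
                             normalize = TRUE) {
  stopifnot(inherits(img, "raw_image"))
  if (is.null(windows)) windows <- full_range_window(img$bit_depth)
  windows <- as_window_set(windows)
  if (nrow(windows) != 1L) {
    rlang::abort("`preprocess_fixed()` takes a single window.",
                 class = "radwindow_error_invalid_window")
  }
  scaled <- apply_affine_window(img$pixels, window_to_affine(windows, 255))
  scaled <- resize_bilinear(scaled, out_size)
  arr <- array(scaled, dim = c(out_size, out_size, 3))
  norm <- NULL
  if (normalize) {
    norm <- imagenet_norm()
    for (j in 1:3) {
      arr[, , j] <- (arr[, , j] / 255 - norm$mean[j]) / norm$std[j]
    }
  }
  structure(list(pixels = arr, normalization = norm), class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<model_input> %dx%dx%d, %s\n", d[1], d[2], d[3],
              if (is.null(x$normalization)) "0-255 scale" else "ImageNet-normalized"))
  invisible(x)
}

#' The 14 chest-radiograph finding classes
#'
#' The standard multi-label vocabulary for chest X-ray classification
#' (atelectasis through support devices), in the conventional order.
#'
#' @return Character vector of length 14.
#' @export
chexpert_classes <- function() {
  c("Atelectasis", "Cardiomegaly", "Consolidation", "Edema",
    "Enlarged Cardiomediastinum", "Fracture", "Lung Lesion",
    "Lung Opacity", "No Finding", "Pleural Effusion", "Pleural Other",
    "Pneumonia", "Pneumothorax", "Support Devices")
}

#' Read a multi-label table
#'
#' Reads a CSV with an image id column, a `split` column (train /
#' validate / test) and the 14 finding columns of [chexpert_classes()].
#' Finding values may be 1 (positive), 0 (negative), -1 (uncertain) or
#' blank (unlabeled, stored as `NA`).
#'
#' @param path CSV path.
#' @return A tibble with columns `image_id`, `split` and one column per
#'   finding class.
#' @export
read_label_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("image_id", "split")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    rlang::abort(paste0("Label table lacks columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "radwindow_error_io")
  }
  bad <- setdiff(tab$split, c("train", "validate", "test"))
  if (length(bad)) {
    rlang::abort(paste0("Unknown split values: ", paste(bad, collapse = ", ")),
                 class = "radwindow_error_io")
  }
  tibble::as_tibble(tab)
}

#' Read an image set from disk
#'
#' Loads the labeled-image-set layout written by [write_image_set()]: a
#' `labels.csv` multi-label table plus one 16-bit image file per row.
#'
#' @param dir Directory containing `labels.csv` and the image files.
#' @param expected_bit_depth Declared pixel bit depth (default 12).
#' @return A `labeled_image_set` (see [generate_dataset()]).
#' @export
read_image_set <- function(dir, expected_bit_depth = 12) {
  labels <- read_label_table(file.path(dir, "labels.csv"))
  files <- file.path(dir, paste0(labels$image_id, ".tif"))
  imgs <- lapply(files, load_image, expected_bit_depth = expected_bit_depth)
  px <- vapply(imgs, function(im) as.numeric(im$pixels),
               numeric(length(imgs[[1]]$pixels)))
  size <- nrow(imgs[[1]]$pixels)
  new_labeled_image_set(px, labels,
                        classes = setdiff(names(labels), c("image_id", "split")),
                        image_size = size, bit_depth = expected_bit_depth)
}

#' Write an image set to disk
#'
#' Writes each image as a 16-bit TIFF named by its image id, plus a
#' `labels.csv` table, the layout [read_image_set()] consumes.
#'
#' @param data A `labeled_image_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(data, dir) {
  stopifnot(inherits(data, "labeled_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(data$labels))) {
    img <- new_raw_image(matrix(data$pixels[, i], data$image_size),
                         data$bit_depth)
    write_image(img, file.path(dir, paste0(data$labels$image_id[i], ".tif")))
  }
  readr::write_csv(data$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
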