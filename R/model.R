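#' Default multi-window initialization set
#'
#' The 14 windows used to initialize the trainable multi-window layer:
#' the union of class-wise top-3 fixed windows selected on validation
#' results of the single-window grid search, plus the full-range
#' "window" (2048, 4096) that leaves 12-bit data untouched.
#'
#' @return A [window_set()] of 14 rows.
#' @export
default_window_init <- function() {
  window_set(
    level = c(100, 1250, 1500, 1750, 1750, 2000, 2250, 2250, 2500, 2500,
              2750, 3250, 750, 2048),
    width = c(3000, 1000, 3000, 2000, 3000, 2000, 2000, 3000, 2000, 3000,
              3000, 1000, 3000, 4096)
  )
}

#' Initialize a trainable window layer
#'
#' Builds the state of a multi-window layer: one clamped-affine channel
#' per window, with channel k's weight and bias set to the
#' [window_to_affine()] image of window k (weight `255/width`, bias
#' `-255/width * (level - width/2)`). Each channel computes
#' `clamp(weight * px + bias, 0, clamp_max)` and both parameters are
#' trainable, so gradient descent moves the windows.
#'
#' @param windows Data frame of initial windows, positive widths.
#' @param clamp_max Output clamp bound (default 255).
#' @return An object of class `window_layer_state` with fields `weight`,
#'   `bias` (length-K numerics), `clamp_max`, `trainable`.
#' @export
init_window_layer <- function(windows, clamp_max = 255) {
  windows <- as_window_set(windows)
  if (nrow(windows) < 1L) {
    rlang::abort("Need at least one window.",
                 class = "radwindow_error_invalid_window")
  }
  aff <- window_to_affine(windows, out_max = clamp_max)
  structure(list(weight = aff$weight, bias = aff$bias,
                 clamp_max = clamp_max, trainable = TRUE),
            class = "window_layer_state")
}

#' Apply a window layer to a single-channel image
#'
#' Pointwise `clamp(weight_k * px + bias_k, 0, clamp_max)` for each of
#' the K channels. Differentiable in the weights, biases and input
#' wherever the output is strictly inside `(0, clamp_max)`, which is
#' what lets the windows be learned end to end.
#'
#' @param image Numeric matrix (single-channel image) or vector.
#' @param state A `window_layer_state` (see [init_window_layer()]).
#' @return For a h x w matrix input, a h x w x K array; for a vector, a
#'   length x K matrix.
#' @export
forward_window_layer <- function(image, state) {
  stopifnot(inherits(state, "window_layer_state"))
  v <- as.numeric(image)
  H <- v %*% t(state$weight)
  H <- sweep(H, 2, state$bias, "+")
  H <- pmin(pmax(H, 0), state$clamp_max)
  if (is.matrix(image)) {
    array(H, dim = c(nrow(image), ncol(image), length(state$weight)))
  } else {
    H
  }
}

#' Recover window settings from a (trained) layer
#'
#' Channelwise inverse of the initialization: `width = clamp_max /
#' weight`, `level = -bias / weight + width / 2`. Channels whose weight
#' became negative are reported as inverted windows (negative width,
#' `inverted = TRUE`); channels with exactly zero weight carry no window
#' and are flagged `degenerate` with `NA` level and width. This is the
#' summary used to inspect which windows a trained model converged to.
#'
#' @param state A `window_layer_state`, or a model built by
#'   [build_model()] in a mode that has a window layer.
#' @return Tibble with columns `channel`, `level`, `width`, `inverted`,
#'   `degenerate`.
#' @export
extract_learned_windows <- function(state) {
  if (inherits(state, "radwindow_model")) state <- state$front
  stopifnot(inherits(state, "window_layer_state"))
  K <- length(state$weight)
  out <- tibble::tibble(channel = seq_len(K),
                        level = NA_real_, width = NA_real_,
                        inverted = FALSE, degenerate = state$weight == 0)
  ok <- !out$degenerate
  if (any(ok)) {
    rec <- affine_to_window(tibble::tibble(weight = state$weight[ok],
                                           bias = state$bias[ok],
                                           out_max = state$clamp_max))
    out$level[ok] <- rec$level
    out$width[ok] <- rec$width
    out$inverted[ok] <- rec$inverted
  }
  out
}

#' Model configuration
#'
#' Describes one of the four architectures compared in this package:
#' \describe{
#'   \item{`baseline`}{fixed full-range preprocessing (optionally after
#'     bit-depth reduction) feeding the backbone directly; no trainable
#'     front-end.}
#'   \item{`windownet`}{trainable multi-window layer (clamped affine
#'     channels initialized from `init_windows`) -> 1x1 K-to-3 channel
#'     mixer -> per-image-channel rescale to `[0, 255]` -> ImageNet
#'     normalization -> backbone.}
#'   \item{`no_windowing`}{same shape as `windownet` but the first layer
#'     is a conventional (unclamped) 1x1 convolution with Kaiming
#'     initialization - the ablation that isolates the effect of
#'     clamping.}
#'   \item{`augmentations`}{the `no_windowing` architecture trained with
#'     random brightness/contrast augmentations (see [train_model()]).}
#' }
#'
#' @param mode One of `"baseline"`, `"windownet"`, `"no_windowing"`,
#'   `"augmentations"`.
#' @param init_windows Windows initializing the window layer
#'   (`windownet` only; defaults to [default_window_init()]).
#' @param num_classes Number of output classes (default 14).
#' @param n_windows Number of first-layer channels K for the ablation
#'   modes (defaults to `nrow(init_windows)`).
#' @param backbone Backbone identifier; `"tiny"` (the built-in backbone:
#'   a pointwise soft intensity-binning encoder, spatial average
#'   pooling, and a one-hidden-layer MLP - no pretrained weights
#'   needed) or a custom backbone: a list with fields `name`,
#'   `init(in_channels, image_size, pool, hidden, num_classes)`,
#'   `forward(params, Zs, Q, norm)` returning `logits` and `cache`, and
#'   `backward(params, cache, dlogits, Q)` returning `grads` and `dZ`.
#' @param image_size Input spatial size (must be divisible by `pool`).
#' @param input_bit_depth Bit depth of raw input pixels (default 12).
#'   The baseline path scales raw pixels by `255 / 2^input_bit_depth`
#'   (the full-range window); set 8 for an 8-bit baseline.
#' @param pool,hidden Tiny-backbone geometry: each soft-bin map is
#'   average-pooled to a `pool` x `pool` grid, and the MLP hidden layer
#'   has width `hidden`.
#' @param seed Seed for the random (Kaiming) initializations.
#' @return A list of class `model_config`.
#' @export
model_config <- function(mode = c("windownet", "baseline", "no_windowing",
                                  "augmentations"),
                         init_windows = NULL, num_classes = 14,
                         n_windows = NULL, backbone = "tiny",
                         image_size = 224, input_bit_depth = 12,
                         pool = 8, hidden = 32, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "windownet") {
    if (is.null(init_windows)) init_windows <- default_window_init()
    init_windows <- as_window_set(init_windows)
    if (nrow(init_windows) < 1L) {
      rlang::abort("windownet mode requires a nonempty `init_windows`.",
                   class = "radwindow_error_invalid_config")
    }
    check_positive_width(init_windows)
    n_windows <- nrow(init_windows)
  } else if (is.null(n_windows)) {
    n_windows <- if (is.null(init_windows)) 14L else nrow(init_windows)
  }
  if (num_classes < 1) {
    rlang::abort("`num_classes` must be at least 1.",
                 class = "radwindow_error_invalid_config")
  }
  if (image_size %% pool != 0) {
    rlang::abort("`image_size` must be divisible by `pool`.",
                 class = "radwindow_error_invalid_config")
  }
  structure(list(mode = mode, init_windows = init_windows,
                 num_classes = as.integer(num_classes),
                 n_windows = as.integer(n_windows), backbone = backbone,
                 image_size = as.integer(image_size),
                 input_bit_depth = as.integer(input_bit_depth),
                 pool = as.integer(pool), hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "model_config")
}

kaiming <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

# block-average pooling operator: (pool^2 x size^2) matrix, row-stochastic
pooling_matrix <- function(size, pool) {
  block <- size %/% pool
  Q <- matrix(0, pool * pool, size * size)
  for (bi in seq_len(pool)) {
    for (bj in seq_len(pool)) {
      rows <- (bi - 1) * block + seq_len(block)
      cols <- (bj - 1) * block + seq_len(block)
      cells <- as.numeric(outer(rows, cols, function(r, c) (c - 1) * size + r))
      Q[(bj - 1) * pool + bi, cells] <- 1 / (block * block)
    }
  }
  Q
}

# The built-in backbone: a pointwise soft intensity-binning encoder
# (radial-basis units centered along the 0-255 output gray scale),
# average-pooled per bin map to a pool x pool grid, classified by a
# one-hidden-layer MLP. The binning gives the classifier access to
# "how much of this region sits at this gray tone", which block means
# alone cannot express, while staying differentiable in the input so
# gradient reaches the window layer.
tiny_bin_centers <- c(0, 64, 128, 192, 255)
tiny_bin_sigma <- 40

tiny_backbone <- function() {
  B <- length(tiny_bin_centers)
  list(
    name = "tiny",
    init = function(in_channels, image_size, pool, hidden, num_classes) {
      n_feat <- in_channels * B * pool * pool
      list(W1 = matrix(kaiming(hidden * n_feat, n_feat), hidden, n_feat),
           b1 = rep(0, hidden),
           W2 = matrix(kaiming(num_classes * hidden, hidden), num_classes,
                       hidden),
           b2 = rep(0, num_classes))
    },
    # Zs: list of normalized channel matrices (pixels x batch); Q: pooling
    forward = function(params, Zs, Q, norm) {
      nC <- length(Zs)
      Fs <- vector("list", nC * B)
      Rs <- vector("list", nC * B)
      for (j in seq_len(nC)) {
        mu <- (tiny_bin_centers / 255 - norm$mean[j]) / norm$std[j]
        sg <- (tiny_bin_sigma / 255) / norm$std[j]
        for (b in seq_len(B)) {
          Rjb <- exp(-(Zs[[j]] - mu[b])^2 / (2 * sg^2))
          Rs[[(j - 1) * B + b]] <- Rjb
          Fs[[(j - 1) * B + b]] <- Q %*% Rjb
        }
      }
      F <- do.call(rbind, Fs)
      H1 <- params$W1 %*% F + params$b1
      R <- pmax(H1, 0)
      logits <- params$W2 %*% R + params$b2
      list(logits = logits,
           cache = list(F = F, H1 = H1, R = R, Rs = Rs, Zs = Zs,
                        norm = norm))
    },
    backward = function(params, cache, dlogits, Q) {
      dR <- crossprod(params$W2, dlogits)
      dH1 <- dR * (cache$H1 > 0)
      dF <- crossprod(params$W1, dH1)
      nQ <- nrow(Q)
      nC <- length(cache$Zs)
      dZ <- vector("list", nC)
      for (j in seq_len(nC)) {
        mu <- (tiny_bin_centers / 255 - cache$norm$mean[j]) / cache$norm$std[j]
        sg <- (tiny_bin_sigma / 255) / cache$norm$std[j]
        dZj <- 0
        for (b in seq_len(B)) {
          rows <- ((j - 1) * B + b - 1) * nQ + seq_len(nQ)
          dRjb <- crossprod(Q, dF[rows, , drop = FALSE])
          dZj <- dZj + dRjb * cache$Rs[[(j - 1) * B + b]] *
            (-(cache$Zs[[j]] - mu[b]) / sg^2)
        }
        dZ[[j]] <- dZj
      }
      list(grads = list(W1 = dH1 %*% t(cache$F), b1 = rowSums(dH1),
                        W2 = dlogits %*% t(cache$R), b2 = rowSums(dlogits)),
           dZ = dZ)
    }
  )
}

#' Build a classifier
#'
#' Assembles the architecture described by a [model_config()]. For the
#' `windownet` mode the window layer is initialized from the configured
#' windows via [init_window_layer()] and the K-to-3 mixer as grouped
#' averaging (windows ordered by level, split into three contiguous
#' groups, one output channel averaging each group - for K < 3, plain
#' averaging), so an untrained model renders low-, mid- and high-band
#' views of the image; the
#' ablation modes use Kaiming-initialized unclamped layers. The backbone
#' sees three ImageNet-normalized channels in all modes.
#'
#' @param cfg A [model_config()].
#' @return An object of class `radwindow_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  withr::with_seed(cfg$seed, {
    K <- cfg$n_windows
    front <- NULL
    mixer <- NULL
    if (cfg$mode == "windownet") {
      front <- init_window_layer(cfg$init_windows, clamp_max = 255)
      # grouped averaging: windows are split by level into three
      # contiguous groups (low / mid / high bands) and each output
      # channel averages one group, so the three backbone channels start
      # as renderings of different intensity regimes rather than three
      # copies of one global average
      if (K >= 3) {
        A <- matrix(0, 3, K)
        groups <- split(order(cfg$init_windows$level),
                        cut(seq_len(K), 3, labels = FALSE))
        for (j in seq_along(groups)) {
          A[j, groups[[j]]] <- 1 / length(groups[[j]])
        }
      } else {
        A <- matrix(1 / K, 3, K)
      }
      mixer <- list(A = A, c = rep(0, 3))
    } else if (cfg$mode %in% c("no_windowing", "augmentations")) {
      front <- structure(list(weight = kaiming(K, 1), bias = rep(0, K),
                              clamp_max = Inf, trainable = TRUE),
                         class = "window_layer_state")
      mixer <- list(A = matrix(kaiming(3 * K, K), 3, K), c = rep(0, 3))
    }
    backbone <- if (identical(cfg$backbone, "tiny")) tiny_backbone()
                else cfg$backbone
    bb_params <- backbone$init(3, cfg$image_size, cfg$pool, cfg$hidden,
                               cfg$num_classes)
    structure(list(cfg = cfg, front = front, mixer = mixer,
                   backbone = backbone, bb_params = bb_params,
                   norm = imagenet_norm(),
                   Q = pooling_matrix(cfg$image_size, cfg$pool)),
              class = "radwindow_model")
  })
}

#' @export
print.radwindow_model <- function(x, ...) {
  cat(sprintf("<radwindow_model> mode %s, %d classes, %dx%d input, backbone %s\n",
              x$cfg$mode, x$cfg$num_classes, x$cfg$image_size,
              x$cfg$image_size, x$backbone$name))
  if (!is.null(x$front)) {
    cat(sprintf("  front layer: %d channels, clamp %s\n",
                length(x$front$weight),
                if (is.finite(x$front$clamp_max))
                  format(x$front$clamp_max) else "none"))
  }
  invisible(x)
}

# --- forward / backward over a batch ---------------------------------------
# Xb: pixels x batch matrix of raw intensities on the input bit scale.

model_forward <- function(model, Xb, want_cache = FALSE) {
  cfg <- model$cfg
  p <- nrow(Xb)
  nb <- ncol(Xb)
  norm <- model$norm
  cache <- list(Xb = Xb)
  if (cfg$mode == "baseline") {
    # fixed full-range window for the declared bit depth, then normalize
    S <- Xb * (255 / 2^cfg$input_bit_depth)
    Zs <- lapply(1:3, function(j) (S / 255 - norm$mean[j]) / norm$std[j])
    cache$base_scale <- 255 / 2^cfg$input_bit_depth
  } else {
    vecX <- as.numeric(Xb)
    H <- vecX %*% t(model$front$weight)
    H <- sweep(H, 2, model$front$bias, "+")
    cmax <- model$front$clamp_max
    if (is.finite(cmax)) {
      mask <- H > 0 & H < cmax
      Hc <- pmin(pmax(H, 0), cmax)
    } else {
      mask <- NULL
      Hc <- H
    }
    M <- Hc %*% t(model$mixer$A)
    M <- sweep(M, 2, model$mixer$c, "+")
    # per image-and-channel min-max rescale onto [0, 255]; the backward
    # pass routes gradient through the min/max statistics via their
    # attaining pixels, so the rescale is differentiated exactly (a.e.)
    Zs <- vector("list", 3)
    fac <- matrix(0, nb, 3)
    rngs <- matrix(0, nb, 3)
    imn <- matrix(0L, nb, 3)
    imx <- matrix(0L, nb, 3)
    Ss <- vector("list", 3)
    for (j in 1:3) {
      Mj <- matrix(M[, j], p, nb)
      mn <- apply(Mj, 2, min)
      mx <- apply(Mj, 2, max)
      rng <- mx - mn
      fj <- ifelse(rng > 1e-8, 255 / rng, 0)
      Sj <- sweep(sweep(Mj, 2, mn, "-"), 2, fj, "*")
      Sj[, rng <= 1e-8] <- 127.5
      Zs[[j]] <- (Sj / 255 - norm$mean[j]) / norm$std[j]
      if (want_cache) {
        fac[, j] <- fj
        rngs[, j] <- rng
        imn[, j] <- apply(Mj, 2, which.min)
        imx[, j] <- apply(Mj, 2, which.max)
        Ss[[j]] <- Sj
      }
    }
    if (want_cache) {
      cache$vecX <- vecX
      cache$mask <- mask
      cache$Hc <- Hc
      cache$fac <- fac
      cache$rngs <- rngs
      cache$imn <- imn
      cache$imx <- imx
      cache$Ss <- Ss
    }
  }
  bb <- model$backbone$forward(model$bb_params, Zs, model$Q, norm)
  if (want_cache) {
    cache$bb <- bb$cache
    list(logits = bb$logits, cache = cache)
  } else {
    list(logits = bb$logits)
  }
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- nrow(cache$Xb)
  nb <- ncol(cache$Xb)
  norm <- model$norm
  bb <- model$backbone$backward(model$bb_params, cache$bb, dlogits, model$Q)
  grads <- list(bb = bb$grads)
  if (cfg$mode != "baseline") {
    dM <- matrix(0, p * nb, 3)
    for (j in 1:3) {
      dSj <- bb$dZ[[j]] / (255 * norm$std[j])
      fj <- cache$fac[, j]
      dMj <- sweep(dSj, 2, fj, "*")
      # gradient through mn and mx, attributed to the attaining pixels:
      # dS/dmn = -f + S/rng at every pixel, dS/dmx = -S/rng
      rng <- cache$rngs[, j]
      live <- rng > 1e-8
      if (any(live)) {
        Sj <- cache$Ss[[j]]
        sum_dS <- colSums(dSj)
        sum_dSS <- colSums(dSj * Sj)
        dmn <- ifelse(live, -fj * sum_dS + sum_dSS / pmax(rng, 1e-12), 0)
        dmx <- ifelse(live, -sum_dSS / pmax(rng, 1e-12), 0)
        cols <- which(live)
        idx_mn <- cbind(cache$imn[cols, j], cols)
        idx_mx <- cbind(cache$imx[cols, j], cols)
        dMj[idx_mn] <- dMj[idx_mn] + dmn[cols]
        dMj[idx_mx] <- dMj[idx_mx] + dmx[cols]
      }
      dM[, j] <- as.numeric(dMj)
    }
    dHc <- dM %*% model$mixer$A
    grads$mixer_A <- crossprod(dM, cache$Hc)
    grads$mixer_c <- colSums(dM)
    dH <- if (is.null(cache$mask)) dHc else dHc * cache$mask
    grads$front_w <- as.numeric(crossprod(dH, cache$vecX))
    grads$front_b <- colSums(dH)
  }
  grads
}

# flat named list of trainable parameter arrays (shared layout with grads)
model_params <- function(model) {
  ps <- list()
  if (model$cfg$mode != "baseline") {
    ps$front_w <- model$front$weight
    ps$front_b <- model$front$bias
    ps$mixer_A <- model$mixer$A
    ps$mixer_c <- model$mixer$c
  }
  for (nm in names(model$bb_params)) {
    ps[[paste0("bb.", nm)]] <- model$bb_params[[nm]]
  }
  ps
}

model_set_params <- function(model, ps) {
  if (model$cfg$mode != "baseline") {
    model$front$weight <- ps$front_w
    model$front$bias <- ps$front_b
    model$mixer$A <- ps$mixer_A
    model$mixer$c <- ps$mixer_c
  }
  for (nm in names(model$bb_params)) {
    model$bb_params[[nm]] <- ps[[paste0("bb.", nm)]]
  }
  model
}

flatten_grads <- function(grads) {
  out <- grads[setdiff(names(grads), "bb")]
  for (nm in names(grads$bb)) out[[paste0("bb.", nm)]] <- grads$bb[[nm]]
  out
}
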