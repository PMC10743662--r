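#' Training configuration
#'
#' The training protocol: binary cross-entropy over the multi-label
#' targets, AdamW with learning rate 1e-4 and batch size 32, learning
#' rate divided by 10 when the validation loss fails to improve for 3
#' consecutive epochs, training stopped after 5 consecutive epochs
#' without validation-loss improvement, and the final model taken from
#' the checkpoint with the highest mean validation AUC.
#'
#' @param learning_rate Initial AdamW learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 32).
#' @param lr_reduce_factor Divisor applied to the learning rate on a
#'   plateau (default 10).
#' @param lr_patience_epochs Epochs without improvement that trigger a
#'   reduction (default 3; the counter restarts after each reduction).
#' @param early_stop_patience_epochs Epochs without improvement that
#'   stop training (default 5).
#' @param max_epochs Safety bound on epochs (default 100; the protocol
#'   itself relies on early stopping).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param improve_tol Absolute decrease in validation loss that counts
#'   as an improvement (default 1e-6).
#' @param uncertain_label_policy How uncertain (-1) labels enter the
#'   loss: `"zeros"` (treat as negative, the default), `"ones"` (treat
#'   as positive) or `"ignore"` (mask out of the loss). Uncertain and
#'   missing labels are always excluded from AUC evaluation.
#' @param seed Seed controlling batch shuffling and augmentation draws.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32,
                         lr_reduce_factor = 10, lr_patience_epochs = 3,
                         early_stop_patience_epochs = 5, max_epochs = 100,
                         weight_decay = 0.01, improve_tol = 1e-6,
                         uncertain_label_policy = c("zeros", "ones", "ignore"),
                         seed = 1) {
  stopifnot(lr_patience_epochs > 0, early_stop_patience_epochs > 0,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 early_stop_patience_epochs =
                   as.integer(early_stop_patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, improve_tol = improve_tol,
                 uncertain_label_policy = match.arg(uncertain_label_policy),
                 seed = as.integer(seed)),
            class = "train_config")
}

# targets in {0,1,NA} plus a mask, after applying the uncertain-label policy
resolve_targets <- function(Y, policy) {
  mask <- !is.na(Y)
  Yp <- Y
  if (policy == "zeros") {
    Yp[!is.na(Y) & Y == -1] <- 0
  } else if (policy == "ones") {
    Yp[!is.na(Y) & Y == -1] <- 1
  } else {
    mask <- mask & (Y != -1)
  }
  Yp[!mask] <- 0
  list(Y = Yp, mask = mask)
}

#' Mean multi-label binary cross-entropy
#'
#' Mean binary cross-entropy over the unmasked (image, class) cells of a
#' multi-label batch, computed from logits in the numerically stable
#' form `max(x, 0) - x y + log(1 + exp(-|x|))`. Uncertain (-1) labels
#' are resolved by `policy`; `NA` labels are always masked out.
#'
#' @param logits Numeric matrix, images x classes.
#' @param targets Matching matrix with values 1, 0, -1 or `NA`.
#' @param policy See [train_config()]'s `uncertain_label_policy`.
#' @return Scalar loss.
#' @examples
#' multilabel_loss(matrix(0, 2, 2), matrix(c(0, 1, 1, 0), 2)) # log(2)
#' @export
multilabel_loss <- function(logits, targets,
                            policy = c("zeros", "ones", "ignore")) {
  policy <- match.arg(policy)
  stopifnot(all(dim(logits) == dim(targets)))
  rt <- resolve_targets(targets, policy)
  if (!any(rt$mask)) {
    rlang::abort("All label cells are masked; loss is undefined.",
                 class = "radwindow_error_undefined_loss")
  }
  x <- logits[rt$mask]
  y <- rt$Y[rt$mask]
  mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
}

# gradient of multilabel_loss wrt logits (same shape as logits)
multilabel_loss_grad <- function(logits, Y, mask) {
  g <- (stats::plogis(logits) - Y) * mask / sum(mask)
  g
}

epochs_since_improvement <- function(losses, tol) {
  best <- cummin(losses)
  improved <- c(TRUE, diff(best) < -tol)
  improved[1] <- TRUE
  length(losses) - max(which(improved))
}

#' Plateau learning-rate schedule step
#'
#' Returns the learning rate to use after the latest epoch: the current
#' rate divided by `lr_reduce_factor` exactly when the validation loss
#' has failed to improve on its running best for `lr_patience_epochs`
#' consecutive epochs. The counter restarts after a reduction, so on a
#' long plateau reductions recur every `lr_patience_epochs` epochs.
#' Improvement means a strict decrease below the best loss seen so far,
#' by more than `improve_tol`.
#'
#' @param val_losses Numeric vector of validation losses, one per epoch,
#'   oldest first.
#' @param current_lr Learning rate used in the latest epoch.
#' @param cfg A [train_config()].
#' @return The (possibly reduced) learning rate.
#' @examples
#' cfg <- train_config()
#' lr_schedule_step(c(1.0, 0.9, 0.8), 1e-4, cfg)        # unchanged
#' lr_schedule_step(c(0.8, 0.9, 0.9, 0.9), 1e-4, cfg)   # divided by 10
#' @export
lr_schedule_step <- function(val_losses, current_lr, cfg = train_config()) {
  stopifnot(length(val_losses) >= 1)
  esi <- epochs_since_improvement(val_losses, cfg$improve_tol)
  if (esi > 0 && esi %% cfg$lr_patience_epochs == 0) {
    current_lr / cfg$lr_reduce_factor
  } else {
    current_lr
  }
}

#' Early-stopping decision
#'
#' `TRUE` exactly when the validation loss has not improved on its
#' running best for `early_stop_patience_epochs` consecutive epochs.
#'
#' @inheritParams lr_schedule_step
#' @return Logical flag.
#' @export
early_stop_decision <- function(val_losses, cfg = train_config()) {
  stopifnot(length(val_losses) >= 1)
  epochs_since_improvement(val_losses, cfg$improve_tol) >=
    cfg$early_stop_patience_epochs
}

# random brightness/contrast augmentation, per image with probability 1/2:
# contrast in [0.8, 1.25] about the image mean, brightness shift up to
# +-20% of the representable range, clipped back to the range
augment_batch <- function(Xb, bit_depth) {
  full <- 2^bit_depth - 1
  nb <- ncol(Xb)
  doit <- stats::runif(nb) < 0.5
  if (!any(doit)) return(Xb)
  contr <- stats::runif(nb, 0.8, 1.25)
  shift <- stats::runif(nb, -0.2, 0.2) * full
  for (i in which(doit)) {
    m <- mean(Xb[, i])
    Xb[, i] <- pmin(pmax(contr[i] * (Xb[, i] - m) + m + shift[i], 0), full)
  }
  Xb
}

adamw_step <- function(ps, grads, state, lr, wd) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  for (nm in names(ps)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    ps[[nm]] <- ps[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * ps[[nm]])
  }
  list(ps = ps, state = state)
}

# batched forward returning images x classes logits
predict_logits <- function(model, X, batch_size = 256) {
  n <- ncol(X)
  out <- matrix(0, n, model$cfg$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[idx, ] <- t(model_forward(model, X[, idx, drop = FALSE])$logits)
  }
  out
}

# mean AUC over classes with both outcomes present; NA-labeled and
# uncertain cells are excluded classwise
mean_val_auc <- function(scores, Y) {
  aucs <- vapply(seq_len(ncol(Y)), function(k) {
    keep <- !is.na(Y[, k]) & Y[, k] %in% c(0, 1)
    if (!any(keep)) return(NA_real_)
    auc(scores[keep, k], Y[keep, k], na_undefined = TRUE)
  }, numeric(1))
  list(mean = mean(aucs, na.rm = TRUE), per_class = aucs,
       n_defined = sum(!is.na(aucs)))
}

#' Train a model
#'
#' Runs the training protocol of [train_config()] on the train split of
#' a labeled image set, evaluating loss and mean AUC on the validation
#' split after every epoch. The learning rate follows the
#' reduce-on-plateau rule, training stops early on a 5-epoch validation
#' plateau, and the returned model is restored to the epoch with the
#' highest mean validation AUC. Deterministic for a fixed seed and data.
#'
#' @param model A [build_model()] result.
#' @param data A `labeled_image_set` with train and validate splits.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `window_fit`: list with the trained
#'   `model`, the per-epoch `log` tibble (train loss, validation loss,
#'   validation mean AUC, learning rate), `selected_epoch`, and the
#'   configs. Supports [tidy()], [glance()] and [autoplot()].
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "radwindow_model"),
            inherits(data, "labeled_image_set"),
            inherits(cfg, "train_config"))
  tr <- split_matrices(data, "train")
  va <- split_matrices(data, "validate")
  rt_tr <- resolve_targets(tr$Y, cfg$uncertain_label_policy)
  rt_va <- resolve_targets(va$Y, cfg$uncertain_label_policy)
  aug <- model$cfg$mode == "augmentations"
  withr::with_seed(cfg$seed, {
    ps <- model_params(model)
    opt <- list(t = 0,
                m = lapply(ps, function(x) x * 0),
                v = lapply(ps, function(x) x * 0))
    lr <- cfg$learning_rate
    n <- ncol(tr$X)
    log <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_mean_auc = numeric(),
                          lr = numeric(), n_auc_classes = integer())
    best_auc <- -Inf
    best_ps <- ps
    best_epoch <- 0L
    val_losses <- numeric()
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        Xb <- tr$X[, idx, drop = FALSE]
        if (aug) Xb <- augment_batch(Xb, model$cfg$input_bit_depth)
        Yb <- rt_tr$Y[idx, , drop = FALSE]
        Mb <- rt_tr$mask[idx, , drop = FALSE]
        if (!any(Mb)) next
        fwd <- model_forward(model, Xb, want_cache = TRUE)
        logits <- t(fwd$logits)  # images x classes
        x <- logits[Mb]
        batch_losses <- c(batch_losses,
                          mean(pmax(x, 0) - x * Yb[Mb] +
                                 log1p(exp(-abs(x)))))
        dlogits <- t(multilabel_loss_grad(logits, Yb, Mb))
        grads <- flatten_grads(model_backward(model, fwd$cache, dlogits))
        upd <- adamw_step(ps, grads, opt, lr, cfg$weight_decay)
        ps <- upd$ps
        opt <- upd$state
        model <- model_set_params(model, ps)
      }
      xv <- predict_logits(model, va$X)
      val_scores <- stats::plogis(xv)
      lv <- multilabel_loss(xv, va$Y, cfg$uncertain_label_policy)
      va_auc <- mean_val_auc(val_scores, va$Y)
      val_losses <- c(val_losses, lv)
      log <- dplyr::bind_rows(log, tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = lv,
        val_mean_auc = va_auc$mean, lr = lr,
        n_auc_classes = va_auc$n_defined))
      if (verbose) {
        message(sprintf(
          "epoch %d: train %.4f  val %.4f  val mAUC %.4f  lr %.1e",
          epoch, mean(batch_losses), lv, va_auc$mean, lr))
      }
      if (is.finite(va_auc$mean) && va_auc$mean > best_auc) {
        best_auc <- va_auc$mean
        best_ps <- ps
        best_epoch <- epoch
      }
      if (early_stop_decision(val_losses, cfg)) break
      lr <- lr_schedule_step(val_losses, lr, cfg)
    }
    model <- model_set_params(model, best_ps)
    structure(list(model = model, log = log,
                   selected_epoch = best_epoch,
                   train_config = cfg, model_config = model$cfg),
              class = "window_fit")
  })
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf("<window_fit> mode %s, %d epochs, checkpoint epoch %d (val mAUC %.4f)\n",
              x$model_config$mode, nrow(x$log), x$selected_epoch,
              x$log$val_mean_auc[x$selected_epoch]))
  invisible(x)
}

#' Predicted class probabilities for a split
#'
#' Runs the (trained) model over one split of a labeled image set and
#' returns sigmoid class probabilities.
#'
#' @param object A `window_fit` or `radwindow_model`.
#' @param data A `labeled_image_set`.
#' @param split Which split to score (default `"test"`).
#' @return A tibble with `image_id` plus one probability column per
#'   class.
#' @export
predict_scores <- function(object, data, split = "test") {
  model <- if (inherits(object, "window_fit")) object$model else object
  stopifnot(inherits(model, "radwindow_model"))
  sm <- split_matrices(data, split)
  probs <- stats::plogis(predict_logits(model, sm$X))
  colnames(probs) <- data$classes
  dplyr::bind_cols(
    tibble::tibble(image_id = data$labels$image_id[sm$idx]),
    tibble::as_tibble(probs)
  )
}
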