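test_that("multi-label cross-entropy matches the per-cell oracle", {
  # logits of zero score every cell at log(2)
  expect_equal(multilabel_loss(matrix(0, 3, 4),
                               matrix(rbinom(12, 1, 0.5), 3, 4)),
               log(2))
  # perfect large-margin predictions drive the loss to zero
  y <- matrix(rbinom(20, 1, 0.5), 4, 5)
  expect_lt(multilabel_loss((2 * y - 1) * 50, y), 1e-12)

  withr::with_seed(12, {
    logits <- matrix(rnorm(24, sd = 2), 4, 6)
    y <- matrix(rbinom(24, 1, 0.4), 4, 6)
  })
  p <- plogis(logits)
  oracle <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(multilabel_loss(logits, y), oracle)
})

test_that("uncertain-label policies remap or mask cells", {
  logits <- matrix(c(1, -1, 2, 0), 2, 2)
  y <- matrix(c(1, -1, NA, 0), 2, 2)
  as0 <- multilabel_loss(logits, y, policy = "zeros")
  as1 <- multilabel_loss(logits, y, policy = "ones")
  ign <- multilabel_loss(logits, y, policy = "ignore")
  y0 <- y; y0[2, 1] <- 0
  y1 <- y; y1[2, 1] <- 1
  expect_equal(as0, multilabel_loss(logits, y0, policy = "ignore"))
  expect_equal(as1, multilabel_loss(logits, y1, policy = "ignore"))
  # with the ignore policy, an all-uncertain image contributes nothing
  expect_equal(ign,
               multilabel_loss(rbind(logits, c(3, -3)),
                               rbind(y, c(-1, -1)), policy = "ignore"))
  expect_error(multilabel_loss(logits, matrix(-1, 2, 2), policy = "ignore"),
               class = "radwindow_error_undefined_loss")
})

test_that("the plateau schedule divides by 10 after three stalled epochs", {
  cfg <- train_config()
  lr <- 1e-4
  expect_equal(lr_schedule_step(c(1.0, 0.9, 0.8), lr, cfg), lr)
  expect_equal(lr_schedule_step(c(0.8, 0.9, 0.9, 0.9), lr, cfg), lr / 10)
  expect_equal(lr_schedule_step(c(0.8, 0.9, 0.7, 0.9), lr, cfg), lr)
  # counter restarts after a reduction: next cut three epochs later
  expect_equal(lr_schedule_step(c(0.8, rep(0.9, 4)), lr / 10, cfg), lr / 10)
  expect_equal(lr_schedule_step(c(0.8, rep(0.9, 6)), lr / 10, cfg), lr / 100)
})

test_that("early stopping fires after five epochs without improvement", {
  cfg <- train_config()
  expect_false(early_stop_decision(c(1, 0.9, 0.8, 0.7, 0.6), cfg))
  expect_true(early_stop_decision(c(0.5, rep(0.6, 5)), cfg))
  expect_false(early_stop_decision(c(0.5, 0.6, 0.6, 0.45, 0.6), cfg))
  expect_false(early_stop_decision(c(0.5, rep(0.6, 4)), cfg))
})

test_that("training returns a per-epoch log and the best-AUC checkpoint", {
  cfg <- tiny_config(seed = 301)
  data <- generate_dataset(cfg)
  m <- build_model(model_config("windownet",
                                init_windows = window_set(
                                  cfg$bands$level, cfg$bands$width),
                                num_classes = 3, image_size = 16, pool = 4,
                                hidden = 8, seed = 1))
  fit <- train_model(m, data, train_config(max_epochs = 2, seed = 9))
  expect_s3_class(fit, "window_fit")
  expect_equal(nrow(fit$log), 2)
  expect_true(fit$selected_epoch %in% c(1, 2))
  # checkpoint-selection invariant
  expect_equal(fit$log$val_mean_auc[fit$selected_epoch],
               max(fit$log$val_mean_auc))
  # learning rate stays on the 1e-4 / 10^m grid
  expect_true(all(abs(log10(1e-4 / fit$log$lr) -
                        round(log10(1e-4 / fit$log$lr))) < 1e-12))
  # tidiers
  expect_equal(tidy(fit), fit$log)
  expect_equal(glance(fit)$selected_epoch, fit$selected_epoch)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- tiny_config(n_train = 40, n_validate = 20, n_test = 10, seed = 77)
  data <- generate_dataset(cfg)
  mk <- function() build_model(model_config(
    "no_windowing", n_windows = 3, num_classes = 3, image_size = 16,
    pool = 4, hidden = 8, seed = 2))
  f1 <- train_model(mk(), data, train_config(max_epochs = 2, seed = 5))
  f2 <- train_model(mk(), data, train_config(max_epochs = 2, seed = 5))
  expect_identical(f1$log, f2$log)
  expect_identical(radwindow:::model_params(f1$model),
                   radwindow:::model_params(f2$model))
})

test_that("training errors on an empty split", {
  cfg <- tiny_config(n_train = 10, n_validate = 5, n_test = 5, seed = 3)
  data <- generate_dataset(cfg)
  data$labels$split[data$labels$split == "validate"] <- "train"
  m <- build_model(model_config("baseline", num_classes = 3,
                                image_size = 16, pool = 4, hidden = 8))
  expect_error(train_model(m, data, train_config(max_epochs = 1)),
               class = "radwindow_error_empty_split")
})

test_that("predicted scores are per-image class probabilities", {
  cfg <- tiny_config(n_train = 20, n_validate = 10, n_test = 10, seed = 41)
  data <- generate_dataset(cfg)
  m <- build_model(model_config("baseline", num_classes = 3,
                                image_size = 16, pool = 4, hidden = 8))
  sc <- predict_scores(m, data, split = "test")
  expect_equal(nrow(sc), 10)
  expect_named(sc, c("image_id", data$classes))
  vals <- as.matrix(sc[, data$classes])
  expect_true(all(vals > 0 & vals < 1))
})
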