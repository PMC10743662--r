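test_that("the default initialization is the 14-window set", {
  ws <- default_window_init()
  expect_equal(nrow(ws), 14)
  expect_equal(ws$level[14], 2048)
  expect_equal(ws$width[14], 4096)
  expect_true(all(ws$width > 0))
  expect_true(all(paste(ws$level, ws$width) %in%
                    paste(c(100, 1250, 1500, 1750, 1750, 2000, 2250, 2250,
                            2500, 2500, 2750, 3250, 750, 2048),
                          c(3000, 1000, 3000, 2000, 3000, 2000, 2000, 3000,
                            2000, 3000, 3000, 1000, 3000, 4096))))
})

test_that("window layer initialization encodes each window exactly", {
  st <- init_window_layer(window_set(2048, 4096))
  expect_equal(st$weight, 255 / 4096)
  expect_equal(st$bias, 0)
  st <- init_window_layer(window_set(1250, 1000))
  expect_equal(st$weight, 0.255)
  expect_equal(st$bias, -191.25)

  st <- init_window_layer(default_window_init())
  rec <- extract_learned_windows(st)
  expect_equal(rec$level, default_window_init()$level, tolerance = 1e-5)
  expect_equal(rec$width, default_window_init()$width, tolerance = 1e-5)
  expect_false(any(rec$inverted))
})

test_that("the window layer forward pass matches the per-channel oracle", {
  img <- random_12bit_image(12, seed = 17)
  ws <- default_window_init()
  st <- init_window_layer(ws)
  H <- forward_window_layer(img, st)
  expect_equal(dim(H), c(12L, 12L, 14L))
  aff <- window_to_affine(ws)
  for (k in 1:14) {
    expect_lt(max(abs(H[, , k] - apply_affine_window(img, aff[k, ]))), 1e-9)
  }
  # K=1 full-range window is the plain linear rescale
  st1 <- init_window_layer(full_range_window())
  expect_equal(forward_window_layer(img, st1)[, , 1], img * 255 / 4096)
  # constant zero image exposes the clamped biases
  st <- init_window_layer(ws)
  H0 <- forward_window_layer(matrix(0, 4, 4), st)
  for (k in 1:14) {
    expect_equal(unique(as.numeric(H0[, , k])),
                 min(max(st$bias[k], 0), 255))
  }
})

test_that("learned-window recovery handles perturbed, inverted and degenerate channels", {
  st <- init_window_layer(default_window_init())
  withr::with_seed(5, {
    st$weight <- st$weight * runif(14, 0.5, 2)
    st$bias <- st$bias + rnorm(14, sd = 20)
  })
  rec <- extract_learned_windows(st)
  # direct substitution of the recovery formulas
  expect_equal(rec$width, 255 / st$weight)
  expect_equal(rec$level, -st$bias / st$weight + 255 / st$weight / 2)

  st$weight[3] <- -st$weight[3]
  st$weight[7] <- 0
  rec <- extract_learned_windows(st)
  expect_true(rec$inverted[3])
  expect_true(rec$degenerate[7])
  expect_true(is.na(rec$level[7]))
})

test_that("model configs validate their invariants", {
  expect_error(model_config("windownet", init_windows = window_set(
    numeric(0), numeric(0))), class = "radwindow_error_invalid_config")
  expect_error(model_config("baseline", num_classes = 0),
               class = "radwindow_error_invalid_config")
  expect_error(model_config("baseline", image_size = 30, pool = 8),
               class = "radwindow_error_invalid_config")
  expect_error(build_model(model_config("windownet",
                                        init_windows = data.frame(level = 1,
                                                                  width = -1))),
               class = "radwindow_error_invalid_window")
})

test_that("built models produce finite logits of the right shape", {
  cfg <- model_config("windownet", num_classes = 14, image_size = 16,
                      pool = 4, hidden = 8, seed = 2)
  m <- build_model(cfg)
  Xb <- matrix(runif(256 * 3, 0, 4095), 256, 3)
  out <- radwindow:::model_forward(m, Xb)
  expect_equal(dim(out$logits), c(14L, 3L))
  expect_true(all(is.finite(out$logits)))
  # a fresh windownet reports its initialization windows
  rec <- extract_learned_windows(m)
  expect_equal(rec$level, default_window_init()$level, tolerance = 1e-5)
})

test_that("clamping bounds the windownet front; the ablation is unbounded", {
  wn <- build_model(model_config("windownet", image_size = 16, pool = 4,
                                 hidden = 8, seed = 3))
  ext <- matrix(c(rep(0, 128), rep(4095, 128)), 256, 1)
  Hwn <- as.numeric(ext) %*% t(wn$front$weight)
  Hwn <- pmin(pmax(sweep(Hwn, 2, wn$front$bias, "+"), 0),
              wn$front$clamp_max)
  expect_true(all(Hwn >= 0 & Hwn <= 255))

  nw <- build_model(model_config("no_windowing", n_windows = 14,
                                 image_size = 16, pool = 4, hidden = 8,
                                 seed = 3))
  Hnw <- as.numeric(ext) %*% t(nw$front$weight)
  Hnw <- sweep(Hnw, 2, nw$front$bias, "+")
  expect_true(any(Hnw < 0 | Hnw > 255))
})

test_that("a K=1 full-range windownet agrees with the 12-bit baseline path", {
  # identical backbone seeds; the only difference is the front end, which
  # for the full-range window plus min-max rescale is the identity on an
  # image that spans the representable range
  cfg_wn <- model_config("windownet", init_windows = full_range_window(),
                         image_size = 16, pool = 4, hidden = 8, seed = 11)
  cfg_bl <- model_config("baseline", image_size = 16, pool = 4, hidden = 8,
                         seed = 11)
  wn <- build_model(cfg_wn)
  bl <- build_model(cfg_bl)
  px <- matrix(round(seq(0, 4095, length.out = 256)), 256, 2)
  lw <- radwindow:::model_forward(wn, px)$logits
  lb <- radwindow:::model_forward(bl, px)$logits
  # the adaptive rescale stretches by 4096/4095 relative to the fixed
  # path (the maximum representable pixel is 4095, the window's upper
  # limit 4096), so agreement is to sub-gray-level, not exact
  expect_equal(lw, lb, tolerance = 1e-2)
})

test_that("analytic gradients match finite differences for every mode", {
  withr::with_seed(19, {
    Xb <- matrix(runif(16 * 16 * 4, 0, 4095), 256, 4)
    Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  })
  Mk <- matrix(TRUE, 4, 3)
  for (mode in c("windownet", "no_windowing", "baseline")) {
    cfg <- if (mode == "windownet") {
      model_config(mode, init_windows = window_set(c(1000, 2600), c(900, 1100)),
                   num_classes = 3, image_size = 16, pool = 4, hidden = 6,
                   seed = 4)
    } else {
      model_config(mode, n_windows = 2, num_classes = 3, image_size = 16,
                   pool = 4, hidden = 6, seed = 4)
    }
    m <- build_model(cfg)
    fwd <- radwindow:::model_forward(m, Xb, want_cache = TRUE)
    dlog <- t(radwindow:::multilabel_loss_grad(t(fwd$logits), Y, Mk))
    grads <- radwindow:::flatten_grads(
      radwindow:::model_backward(m, fwd$cache, dlog))
    ps <- radwindow:::model_params(m)
    lossfun <- function(mm) {
      multilabel_loss(t(radwindow:::model_forward(mm, Xb)$logits), Y)
    }
    eps <- 1e-5
    withr::with_seed(33, {
      for (nm in names(ps)) {
        for (i in sample(length(ps[[nm]]), min(3, length(ps[[nm]])))) {
          p2 <- ps
          p2[[nm]][i] <- p2[[nm]][i] + eps
          up <- lossfun(radwindow:::model_set_params(m, p2))
          p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
          dn <- lossfun(radwindow:::model_set_params(m, p2))
          fd <- (up - dn) / (2 * eps)
          expect_lt(abs(fd - grads[[nm]][i]), 1e-5 + 2e-2 * abs(fd))
        }
      }
    })
  }
})
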