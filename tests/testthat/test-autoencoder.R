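test_that("activation primitives follow their definitions", {
  expect_equal(relu(c(-1, 2), diag(2), c(0, 0)), c(0, 2))
  expect_equal(relu(c(5, 5), matrix(0, 2, 1), -3), 0)
  set.seed(1)
  x <- rnorm(50)
  expect_true(all(relu(x, diag(50), 0) >= 0))
  expect_identical(tanh_act(0), 0)
  expect_lt(abs(tanh_act(20) - 1), 1e-12)
  expect_equal(tanh_act(-x), -tanh_act(x))
  expect_equal(rrelu(2, 1 / 8), 2)
  expect_equal(rrelu(-8, 1 / 8), -1)
  expect_error(rrelu(-1, 0.5), "lambda")
  # sampled slopes stay inside the stated band during training
  xn <- matrix(-runif(100), 10)
  r <- cryohetero:::rrelu_fw(xn, training = TRUE)
  expect_true(all(r$y / xn >= 1 / 8 & r$y / xn <= 1 / 3))
  expect_true(all(r$slope >= 1 / 8 & r$slope <= 1 / 3))
})

test_that("mse_loss is the mean squared difference", {
  expect_identical(mse_loss(c(1, 1), c(1, 1)), 0)
  expect_identical(mse_loss(c(1, 1), c(0, 0)), 1)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_error(mse_loss(a, rnorm(5)), "shape")
})

test_that("AE-MLP has the 4096-512-8 architecture and bounded outputs", {
  m <- build_ae_mlp(seed = 1)
  expect_identical(m$latent_dim, 8L)
  expect_identical(m$arch$layers, c(4096L, 512L, 8L, 512L, 4096L))
  # encoder parameter count: 4096*512 + 512 + 512*8 + 8
  expect_identical(ae_param_count(m, "encoder"), 2101768)
  X <- matrix(runif(2 * 4096, -1, 1), 2)
  out <- cryohetero:::mlp_pass(m$params, X, want_grads = FALSE)
  expect_identical(dim(out$Y), dim(X))
  expect_true(all(out$Y > -1 & out$Y < 1))
  expect_identical(dim(out$Z), c(2L, 8L))
})

test_that("AE-MLP analytic gradients agree with central differences", {
  m <- build_ae_mlp(seed = 4)
  set.seed(2)
  X <- matrix(runif(2 * 4096, -1, 1), 2)
  out <- cryohetero:::mlp_pass(m$params, X)
  for (layer in c("enc1", "enc2", "dec1", "dec2")) {
    for (fld in c("W", "b")) {
      idx <- 3L
      num <- local({
        p <- m$params; eps <- 1e-6
        p[[layer]][[fld]][idx] <- p[[layer]][[fld]][idx] + eps
        l1 <- cryohetero:::mlp_pass(p, X, want_grads = FALSE)$loss
        p[[layer]][[fld]][idx] <- p[[layer]][[fld]][idx] - 2 * eps
        l2 <- cryohetero:::mlp_pass(p, X, want_grads = FALSE)$loss
        (l1 - l2) / (2 * eps)
      })
      # training gradient uses the per-image-sum convention (4096x the
      # per-element-mean derivative measured here)
      an <- out$grads[[layer]][[fld]][idx] / 4096
      expect_equal(an, num, tolerance = 1e-4)
    }
  }
})

test_that("AE-RES has the stated module counts, ladders and latent size", {
  r <- build_ae_res(seed = 1)
  expect_identical(r$latent_dim, 4096L)
  expect_identical(r$arch$n_resdown, 5L)
  expect_identical(r$arch$n_resup, 6L)
  expect_identical(r$arch$enc_spatial, c(64L, 32L, 16L, 8L, 4L, 2L, 1L))
  expect_identical(r$arch$dec_spatial, c(1L, 2L, 4L, 8L, 16L, 32L, 64L))
  # trace shapes through the encoder
  x <- array(runif(64 * 64 * 3 * 2, -1, 1), c(64, 64, 3, 2))
  h <- cryohetero:::conv_fw(x, r$params$conv_in, 1L)
  sizes <- dim(h)[1]
  for (i in 1:5) {
    h <- cryohetero:::res_fw(h, r$params[[paste0("rd", i)]], FALSE, "down")$y
    sizes <- c(sizes, dim(h)[1])
  }
  lat <- cryohetero:::conv_fw(h, r$params$conv_latent, 0L)
  sizes <- c(sizes, dim(lat)[1])
  expect_identical(sizes, c(64L, 32L, 16L, 8L, 4L, 2L, 1L))
  expect_identical(dim(lat)[3], 4096L)
  # full forward returns the input shape with Tanh-bounded values
  out <- cryohetero:::res_pass(r$params, x, training = FALSE,
                               want_grads = FALSE)
  expect_identical(dim(out$Y), dim(x))
  expect_true(all(out$Y > -1 & out$Y < 1))
})

test_that("conv, pooling, upsampling and batch-norm backward passes are exact", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  p <- cryohetero:::init_conv(2, 4, 3)
  y <- cryohetero:::conv_fw(x, p, 1L)
  dy <- array(rnorm(length(y)), dim = dim(y))
  bw <- cryohetero:::conv_bw(x, p, dy, 1L)
  eps <- 1e-6
  for (idx in c(1L, 17L)) {
    pp <- p; pp$W[idx] <- pp$W[idx] + eps
    lp <- sum(cryohetero:::conv_fw(x, pp, 1L) * dy)
    pp$W[idx] <- pp$W[idx] - 2 * eps
    lm <- sum(cryohetero:::conv_fw(x, pp, 1L) * dy)
    expect_equal(bw$dW[idx], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  xx <- x; xx[10] <- xx[10] + eps
  lp <- sum(cryohetero:::conv_fw(xx, p, 1L) * dy)
  xx[10] <- xx[10] - 2 * eps
  lm <- sum(cryohetero:::conv_fw(xx, p, 1L) * dy)
  expect_equal(bw$dx[10], (lp - lm) / (2 * eps), tolerance = 1e-5)
  # avgpool / upsample are exact linear adjoints
  yp <- cryohetero:::.avgpool2_fw_cpp(x, dim(x))
  dyp <- array(rnorm(length(yp)), dim = dim(yp))
  expect_equal(sum(cryohetero:::.avgpool2_bw_cpp(dyp, dim(dyp)) * x), sum(dyp * yp),
               tolerance = 1e-10)
  yu <- cryohetero:::.upsample2_fw_cpp(x, dim(x))
  dyu <- array(rnorm(length(yu)), dim = dim(yu))
  expect_equal(sum(cryohetero:::.upsample2_bw_cpp(dyu, dim(dyu)) * x), sum(dyu * yu),
               tolerance = 1e-10)
  # batch norm backward (training statistics)
  bp <- cryohetero:::init_bn(2)
  fw <- cryohetero:::bn_fw(x, bp, training = TRUE)
  dyb <- array(rnorm(length(x)), dim = dim(x))
  bb <- cryohetero:::bn_bw(dyb, fw$cache)
  xx <- x; xx[5] <- xx[5] + eps
  lp <- sum(cryohetero:::bn_fw(xx, bp, TRUE)$y * dyb)
  xx[5] <- xx[5] - 2 * eps
  lm <- sum(cryohetero:::bn_fw(xx, bp, TRUE)$y * dyb)
  expect_equal(bb$dx[5], (lp - lm) / (2 * eps), tolerance = 1e-4)
})

test_that("training reduces the loss and is deterministic", {
  stack <- make_tiny_stack(K = 2, per_class = 20, size = 64, snr = 1e6)
  pre <- preprocess_stack(stack, channels = 1)
  cfg <- training_config("mlp", max_epochs = 30, seed = 5)
  m <- train_autoencoder(build_ae_mlp(5), pre, cfg)
  expect_length(m$loss_history, 30)
  expect_lt(m$loss_history[30], m$loss_history[1])
  m2 <- train_autoencoder(build_ae_mlp(5), pre, cfg)
  expect_identical(m$loss_history, m2$loss_history)
  expect_error(train_autoencoder(build_ae_mlp(5), pre,
                                 training_config("res")), "kind")
})

test_that("trained AE-MLP beats the best constant predictor on clean data", {
  stack <- make_tiny_stack(K = 2, per_class = 30, size = 64, snr = 1e6)
  pre <- preprocess_stack(stack, channels = 1)
  cfg <- training_config("mlp", max_epochs = 150, seed = 2)
  m <- train_autoencoder(build_ae_mlp(2), pre, cfg)
  const_loss <- mean(apply(pre$images[, , 1, ], 3,
                           function(im) mean((im - mean(im))^2)))
  expect_lt(ae_reconstruct(m, pre)$loss, const_loss)
})

test_that("one-pass AE-RES training performs exactly ceil(N/32) updates", {
  stack <- make_tiny_stack(K = 2, per_class = 20, size = 64, snr = 1)
  pre <- preprocess_stack(stack, channels = 3)
  cfg <- training_config("res", seed = 3)
  expect_identical(cfg$max_epochs, 1L)
  r <- train_autoencoder(build_ae_res(3), pre, cfg)
  expect_length(r$loss_history, 1)
  # the batch-norm layers saw every minibatch exactly once
  expect_identical(r$params$rd1$bn1$n_batches, ceiling(40 / 32))
})

test_that("latent extraction is a pure evaluation-mode function", {
  stack <- make_tiny_stack(K = 2, per_class = 8, size = 64, snr = 1)
  pre1 <- preprocess_stack(stack, channels = 1)
  m <- build_ae_mlp(1)
  Z <- extract_latents(m, pre1)
  expect_identical(dim(Z), c(16L, 8L))
  r <- build_ae_res(1)
  pre3 <- preprocess_stack(stack, channels = 3)
  Zr <- extract_latents(r, pre3)
  expect_identical(dim(Zr), c(16L, 4096L))
  # duplicate images map to identical latent rows
  dup <- pre3
  dup$images[, , , 2] <- dup$images[, , , 1]
  Zd <- extract_latents(r, dup)
  expect_identical(Zd[1, ], Zd[2, ])
  expect_error(extract_latents(m, pre3), "channel")
})

test_that("checkpoints round-trip through disk", {
  m <- build_ae_mlp(8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ae_model(m, path)
  m2 <- load_ae_model(path)
  expect_identical(m2$params, m$params)
})
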