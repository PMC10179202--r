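# The two autoencoder architectures. AE-MLP: symmetric three-layer dense
# encoder/decoder (4096-512-8 / 8-512-4096), iterative training. AE-RES:
# asymmetric convolutional model -- encoder = input conv + five residual
# downsampling blocks (64->32->16->8->4->2) + a kernel-2 valid conv to a
# 4096-D latent; decoder = six residual upsampling blocks (1->2->...->64) +
# output conv + Tanh. Residual blocks combine an avgpool/upsample+conv path
# with a conv-BN-RReLU-pool-conv-BN path by elementwise addition, then RReLU.

AE_RES_ENC_CHANNELS <- c(16, 32, 64, 64, 128)  # ResDown outputs
AE_RES_DEC_CHANNELS <- c(64, 64, 32, 32, 16, 16)  # ResUp outputs
AE_RES_BASE <- 16L

#' Build the multi-layer-perceptron autoencoder (AE-MLP)
#'
#' Encoder: flattened 64x64 image (4096) -> ReLU dense layer with 512
#' neurons -> linear map to an 8-D latent. Decoder mirrors it: 8 -> ReLU
#' dense 512 -> linear 4096 -> Tanh, reshaped to 64x64. Weights and biases
#' are initialised uniformly at `+/- 1/sqrt(fan_in)` from `seed`.
#'
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `cryo_ae` with `kind = "mlp"`,
#'   `latent_dim = 8`.
#' @export
build_ae_mlp <- function(seed = 1) {
  params <- with_seed(derive_seed(seed, "init-mlp"), list(
    enc1 = init_dense(4096, 512),
    enc2 = init_dense(512, 8),
    dec1 = init_dense(8, 512),
    dec2 = init_dense(512, 4096)))
  structure(list(kind = "mlp", latent_dim = 8L, channels = 1L,
                 params = params, loss_history = numeric(0), trained = FALSE,
                 arch = list(layers = c(4096L, 512L, 8L, 512L, 4096L),
                             activations = c("relu", "linear", "relu", "tanh"))),
            class = "cryo_ae")
}

#' Build the residual convolutional autoencoder (AE-RES)
#'
#' Encoder: input 3x64x64 -> 3x3 conv -> five ResDown modules halving the
#' spatial size 64->32->16->8->4->2 -> kernel-2 valid convolution to a
#' 1x1x4096 latent. Decoder: latent reshaped to 1x1 spatial -> six ResUp
#' modules doubling 1->2->4->8->16->32->64 -> 3x3 conv to 3 channels -> Tanh.
#' Designed for one-pass (single-epoch) training.
#'
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `cryo_ae` with `kind = "res"`,
#'   `latent_dim = 4096`.
#' @export
build_ae_res <- function(seed = 1) {
  enc_ch <- AE_RES_ENC_CHANNELS
  dec_ch <- AE_RES_DEC_CHANNELS
  params <- with_seed(derive_seed(seed, "init-res"), {
    p <- list(conv_in = init_conv(3, AE_RES_BASE, 3))
    cin <- AE_RES_BASE
    for (i in seq_along(enc_ch)) {
      p[[paste0("rd", i)]] <- init_resblock(cin, enc_ch[i])
      cin <- enc_ch[i]
    }
    p$conv_latent <- init_conv(cin, 4096, 2)
    cin <- 4096
    for (i in seq_along(dec_ch)) {
      p[[paste0("ru", i)]] <- init_resblock(cin, dec_ch[i])
      cin <- dec_ch[i]
    }
    p$conv_out <- init_conv(cin, 3, 3)
    p
  })
  structure(list(kind = "res", latent_dim = 4096L, channels = 3L,
                 params = params, loss_history = numeric(0), trained = FALSE,
                 arch = list(n_resdown = 5L, n_resup = 6L,
                             enc_channels = enc_ch, dec_channels = dec_ch,
                             enc_spatial = c(64L, 32L, 16L, 8L, 4L, 2L, 1L),
                             dec_spatial = c(1L, 2L, 4L, 8L, 16L, 32L, 64L))),
            class = "cryo_ae")
}

#' @export
print.cryo_ae <- function(x, ...) {
  cat(sprintf("<cryo_ae> kind=%s latent_dim=%d trained=%s params=%s\n",
              x$kind, x$latent_dim, x$trained,
              format(ae_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Count the trainable parameters of an autoencoder
#'
#' @param model a `cryo_ae`.
#' @param part `"all"`, `"encoder"` or `"decoder"`.
#' @return Integer parameter count (weights + biases; batch-norm scale and
#'   shift included, running statistics excluded).
#' @export
ae_param_count <- function(model, part = "all") {
  enc_names <- if (model$kind == "mlp") c("enc1", "enc2") else
    c("conv_in", paste0("rd", 1:5), "conv_latent")
  dec_names <- if (model$kind == "mlp") c("dec1", "dec2") else
    c(paste0("ru", 1:6), "conv_out")
  names <- switch(part, all = c(enc_names, dec_names), encoder = enc_names,
                  decoder = dec_names, stop("unknown part"))
  count1 <- function(p) {
    if (!is.null(p$W)) return(length(p$W) + length(p$b))
    # residual block
    sum(vapply(p, function(q) {
      if (!is.null(q$k)) length(q$W) + length(q$b)
      else length(q$gamma) + length(q$beta)
    }, numeric(1)))
  }
  sum(vapply(model$params[names], count1, numeric(1)))
}

init_resblock <- function(cin, cout) {
  list(convA = init_conv(cin, cout, 3),
       conv1 = init_conv(cin, cout, 3), bn1 = init_bn(cout),
       conv2 = init_conv(cout, cout, 3), bn2 = init_bn(cout))
}

# ---- residual block forward/backward -----------------------------------
# `resample` is avgpool for ResDown, upsample for ResUp; both paths resample
# at the same point so their outputs align spatially.

res_fw <- function(x, p, training, kind) {
  resample_fw <- if (kind == "down") .avgpool2_fw_cpp else .upsample2_fw_cpp
  xr <- resample_fw(x, dim(x))
  A <- conv_fw(xr, p$convA, pad = 1L)
  B1 <- conv_fw(x, p$conv1, pad = 1L)
  bn1 <- bn_fw(B1, p$bn1, training)
  r1 <- rrelu_fw(bn1$y, training)
  B4 <- resample_fw(r1$y, dim(r1$y))
  B5 <- conv_fw(B4, p$conv2, pad = 1L)
  bn2 <- bn_fw(B5, p$bn2, training)
  S <- A + bn2$y
  r2 <- rrelu_fw(S, training)
  p$bn1 <- bn1$p
  p$bn2 <- bn2$p
  list(y = r2$y, p = p,
       cache = list(x = x, xr = xr, B1 = B1, bn1 = bn1$cache, r1 = r1,
                    B4 = B4, bn2 = bn2$cache, r2slope = r2$slope))
}

res_bw <- function(dy, p, cache, kind) {
  resample_bw <- if (kind == "down") .avgpool2_bw_cpp else .upsample2_bw_cpp
  dS <- dy * cache$r2slope
  # path A
  gA <- conv_bw(cache$xr, p$convA, dS, pad = 1L)
  dx_a <- resample_bw(gA$dx, dim(gA$dx))
  # path B
  b2 <- bn_bw(dS, cache$bn2)
  g2 <- conv_bw(cache$B4, p$conv2, b2$dx, pad = 1L)
  dB3 <- resample_bw(g2$dx, dim(g2$dx))
  dB2 <- dB3 * cache$r1$slope
  b1 <- bn_bw(dB2, cache$bn1)
  g1 <- conv_bw(cache$x, p$conv1, b1$dx, pad = 1L)
  grads <- list(convA = list(W = gA$dW, b = gA$db),
                conv1 = list(W = g1$dW, b = g1$db),
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(W = g2$dW, b = g2$db),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  list(dx = dx_a + g1$dx, grads = grads)
}

# ---- full-model passes --------------------------------------------------

# X: B x 4096 matrix. Returns loss, latent Z and parameter gradients.
mlp_pass <- function(params, X, want_grads = TRUE) {
  p <- params
  H1p <- sweep(X %*% p$enc1$W, 2, p$enc1$b, `+`)
  H1 <- pmax(H1p, 0)
  Z <- sweep(H1 %*% p$enc2$W, 2, p$enc2$b, `+`)
  H2p <- sweep(Z %*% p$dec1$W, 2, p$dec1$b, `+`)
  H2 <- pmax(H2p, 0)
  Yp <- sweep(H2 %*% p$dec2$W, 2, p$dec2$b, `+`)
  Y <- tanh(Yp)
  loss <- mean((X - Y)^2)
  if (!want_grads) return(list(loss = loss, Z = Z, Y = Y))
  # training objective: batch mean of the per-image summed squared error
  # (the per-pixel mean would scale gradients down by 64*64 and stall SGD at
  # the standard learning rate); reported losses stay per-pixel means
  dY <- 2 * (Y - X) / nrow(X)
  dYp <- dY * (1 - Y^2)
  gdec2 <- list(W = crossprod(H2, dYp), b = colSums(dYp))
  dH2 <- tcrossprod(dYp, p$dec2$W) * (H2p > 0)
  gdec1 <- list(W = crossprod(Z, dH2), b = colSums(dH2))
  dZ <- tcrossprod(dH2, p$dec1$W)
  genc2 <- list(W = crossprod(H1, dZ), b = colSums(dZ))
  dH1 <- tcrossprod(dZ, p$enc2$W) * (H1p > 0)
  genc1 <- list(W = crossprod(X, dH1), b = colSums(dH1))
  list(loss = loss, Z = Z, Y = Y,
       grads = list(enc1 = genc1, enc2 = genc2, dec1 = gdec1, dec2 = gdec2))
}

# x: 64 x 64 x 3 x B array. Forward (and optionally backward) pass of the
# residual model. Returns updated params (batch-norm running stats change in
# training mode).
res_pass <- function(params, x, training, want_grads = TRUE) {
  p <- params
  caches <- list()
  h <- conv_fw(x, p$conv_in, pad = 1L)
  conv_in_x <- x
  for (i in 1:5) {
    r <- res_fw(h, p[[paste0("rd", i)]], training, "down")
    p[[paste0("rd", i)]] <- r$p
    caches[[paste0("rd", i)]] <- r$cache
    h <- r$y
  }
  enc_in <- h                              # 2 x 2 x C x B
  lat <- conv_fw(h, p$conv_latent, pad = 0L)  # 1 x 1 x 4096 x B
  B <- dim(x)[4]
  Z <- matrix(lat, nrow = 4096, ncol = B)  # latent per column
  h <- lat
  for (i in 1:6) {
    r <- res_fw(h, p[[paste0("ru", i)]], training, "up")
    p[[paste0("ru", i)]] <- r$p
    caches[[paste0("ru", i)]] <- r$cache
    h <- r$y
  }
  dec_in <- h
  Yp <- conv_fw(h, p$conv_out, pad = 1L)
  Y <- tanh(Yp)
  loss <- mean((x - Y)^2)
  if (!want_grads)
    return(list(loss = loss, Z = t(Z), Y = Y, p = p))
  grads <- list()
  # per-element mean objective: the conv stack's gradients accumulate over
  # every spatial position, so the image-sum convention used for the dense
  # model would saturate the output Tanh in a single step at the standard
  # learning rate
  dY <- 2 * (Y - x) / length(x)
  dYp <- dY * (1 - Y^2)
  g <- conv_bw(dec_in, p$conv_out, dYp, pad = 1L)
  grads$conv_out <- list(W = g$dW, b = g$db)
  dh <- g$dx
  for (i in 6:1) {
    r <- res_bw(dh, p[[paste0("ru", i)]], caches[[paste0("ru", i)]], "up")
    grads[[paste0("ru", i)]] <- r$grads
    dh <- r$dx
  }
  g <- conv_bw(enc_in, p$conv_latent, dh, pad = 0L)
  grads$conv_latent <- list(W = g$dW, b = g$db)
  dh <- g$dx
  for (i in 5:1) {
    r <- res_bw(dh, p[[paste0("rd", i)]], caches[[paste0("rd", i)]], "down")
    grads[[paste0("rd", i)]] <- r$grads
    dh <- r$dx
  }
  g <- conv_bw(conv_in_x, p$conv_in, dh, pad = 1L)
  grads$conv_in <- list(W = g$dW, b = g$db)
  list(loss = loss, Z = t(Z), Y = Y, p = p, grads = grads)
}

# encoder-only evaluation pass for the residual model
res_encode <- function(params, x) {
  h <- conv_fw(x, params$conv_in, pad = 1L)
  for (i in 1:5) h <- res_fw(h, params[[paste0("rd", i)]], FALSE, "down")$y
  lat <- conv_fw(h, params$conv_latent, pad = 0L)
  t(matrix(lat, nrow = 4096, ncol = dim(x)[4]))
}

sgd_update <- function(params, grads, lr) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (!is.null(g$W)) {
      params[[nm]]$W <- params[[nm]]$W - lr * g$W
      params[[nm]]$b <- params[[nm]]$b - lr * g$b
    } else {
      for (sub in names(g)) {
        for (fld in names(g[[sub]])) {
          params[[nm]][[sub]][[fld]] <-
            params[[nm]][[sub]][[fld]] - lr * g[[sub]][[fld]]
        }
      }
    }
  }
  params
}
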