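# Activation primitives and layer forward/backward passes used by both
# autoencoder models. Dense layers run on BLAS matmuls; convolution, pooling
# and upsampling are the compiled im2col kernels in src/.

#' Affine-ReLU activation
#'
#' Computes `max(0, t(w) %*% x + b)` elementwise, the rectified linear unit
#' applied to an affine map.
#'
#' @param x numeric vector (input).
#' @param w weight matrix with `nrow(w) == length(x)`.
#' @param b bias vector with `length(b) == ncol(w)`.
#' @return Nonnegative numeric vector of length `ncol(w)`.
#' @export
#' @examples
#' relu(c(-1, 2), diag(2), c(0, 0))
relu <- function(x, w = diag(length(x)), b = 0) {
  if (nrow(w) != length(x)) stop("shape mismatch between w and x")
  pmax(0, drop(crossprod(w, x)) + b)
}

#' Hyperbolic tangent activation
#'
#' `(exp(x) - exp(-x)) / (exp(x) + exp(-x))`; odd, bounded in (-1, 1). This
#' bound is what forces the autoencoder inputs to be normalised to `[-1, 1]`.
#'
#' @param x numeric.
#' @return `tanh(x)`.
#' @export
tanh_act <- function(x) tanh(x)

#' Randomized leaky ReLU
#'
#' `x` for `x >= 0`, otherwise `lambda * x`. During training the slope is
#' drawn per element from U(1/8, 1/3); at evaluation the fixed midpoint
#' `(1/8 + 1/3)/2` is used, which is the default here.
#'
#' @param x numeric.
#' @param lambda_ negative-branch slope in `[1/8, 1/3]`.
#' @return Numeric of the same shape.
#' @export
#' @examples
#' rrelu(-8, lambda_ = 1/8)
rrelu <- function(x, lambda_ = (1 / 8 + 1 / 3) / 2) {
  if (any(lambda_ < 1 / 8 - 1e-12) || any(lambda_ > 1 / 3 + 1e-12))
    stop("lambda_ must lie in [1/8, 1/3]")
  ifelse(x >= 0, x, lambda_ * x)
}

#' Mean squared error between two batches
#'
#' Mean over every element of `(y - y_hat)^2`; the reconstruction loss of
#' both autoencoders.
#'
#' @param y,y_hat numeric arrays of identical shape.
#' @return Nonnegative scalar.
#' @export
mse_loss <- function(y, y_hat) {
  if (!identical(dim(y), dim(y_hat)) || length(y) != length(y_hat))
    stop("shape mismatch")
  mean((y - y_hat)^2)
}

# ---- internal layer machinery ------------------------------------------

init_dense <- function(nin, nout) {
  s <- 1 / sqrt(nin)
  list(W = matrix(runif(nin * nout, -s, s), nin, nout),
       b = runif(nout, -s, s))
}

init_conv <- function(cin, cout, k) {
  s <- 1 / sqrt(cin * k * k)
  list(W = matrix(runif(cin * k * k * cout, -s, s), cin * k * k, cout),
       b = runif(cout, -s, s), k = k)
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       running_mean = rep(0, c), running_var = rep(1, c), n_batches = 0)
}

conv_fw <- function(x, p, pad) .conv2d_fw_cpp(x, dim(x), p$W, p$b, p$k, p$k, pad)

conv_bw <- function(x, p, dy, pad) .conv2d_bw_cpp(x, dim(x), p$W, dy, p$k, p$k, pad)

# channel-major reshape helpers for batch norm: (H,W,C,B) <-> (H*W*B, C)
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

from_cmat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

bn_fw <- function(x, p, training, eps = 1e-5) {
  d <- dim(x)
  m <- to_cmat(x)
  nm <- nrow(m)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    v <- colMeans(xc^2)
    # cumulative moving average so the running statistics are calibrated
    # even after a single one-pass epoch
    p$n_batches <- p$n_batches + 1
    momentum <- 1 / p$n_batches
    p$running_mean <- (1 - momentum) * p$running_mean + momentum * mu
    vu <- if (nm > 1) v * nm / (nm - 1) else v
    p$running_var <- (1 - momentum) * p$running_var + momentum * vu
  } else {
    mu <- p$running_mean
    v <- p$running_var
    xc <- sweep(m, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = from_cmat(y, d), p = p,
       cache = list(xhat = xhat, istd = istd, d = d, gamma = p$gamma))
}

bn_bw <- function(dy, cache) {
  d <- cache$d
  dym <- to_cmat(dy)
  nm <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, `*`)
  # dx = istd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2, colSums(dxhat) / nm)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / nm, `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dx = from_cmat(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# RReLU with per-element random slope when training; returns slope mask for
# the backward pass.
rrelu_fw <- function(x, training) {
  slope <- array(1, dim = dim(x))
  neg <- x < 0
  if (any(neg)) {
    slope[neg] <- if (training) runif(sum(neg), 1 / 8, 1 / 3) else 11 / 48
  }
  list(y = x * slope, slope = slope)
}
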