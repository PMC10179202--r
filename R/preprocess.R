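# FFT index helpers shared by the preprocessing, reconstruction and FSC code.
fftshift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
ifftshift_idx <- function(n) c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2)))

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m))]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m))]

fftshift3 <- function(a) {
  i <- fftshift_idx(dim(a)[1])
  a[i, i, i]
}
ifftshift3 <- function(a) {
  i <- ifftshift_idx(dim(a)[1])
  a[i, i, i]
}

#' Downsample a square image by Fourier cropping
#'
#' Truncates the centred 2D DFT to the central `target x target` band and
#' inverse-transforms, keeping the real part. This exactly band-limits the
#' image, preserves its mean, and removes the high-frequency part of the
#' noise, which is why downsampling acts as preliminary denoising of cryo-EM
#' projections.
#'
#' @param image square numeric matrix of side `n >= target`.
#' @param target output side length (upsampling is not supported).
#' @return `target x target` numeric matrix.
#' @export
downsample_image <- function(image, target) {
  n <- nrow(image)
  if (!is.matrix(image) || n != ncol(image)) stop("image must be square")
  if (n < target) stop("target exceeds image size; upsampling is not supported")
  if (n == target) return(image)
  Fc <- fftshift2(fft(ifftshift2(image)))
  cn <- floor(n / 2) + 1
  keep <- (cn - floor(target / 2)):(cn + ceiling(target / 2) - 1)
  Fc <- Fc[keep, keep]
  fftshift2(Re(fft(ifftshift2(Fc), inverse = TRUE))) / (n * n)
}

#' Replicate a single-channel image to three channels
#'
#' @param image either a `64 x 64` matrix or an `H x W x 1` array.
#' @return `H x W x 3` array with three identical channels.
#' @export
replicate_channels <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  if (length(dim(image)) != 3 || dim(image)[3] != 1)
    stop("input must be single-channel")
  array(image, dim = c(dim(image)[1:2], 1, 3))[, , 1, ]
}

#' Preprocess a particle stack for autoencoder input
#'
#' Step 1 of the pipeline: each projection image is Fourier-cropped to
#' `target x target` (64 by default), then independently min-max normalised
#' to `[-1, 1]` (the decoder output passes through Tanh, so the target range
#' must be bounded), and optionally replicated to three channels for the
#' residual model. The per-image mapping parameters are recorded so the
#' normalisation is invertible.
#'
#' @param stack a `cryo_stack`.
#' @param channels 1 (MLP autoencoder) or 3 (residual autoencoder).
#' @param target output image side, default 64.
#' @return An object of class `cryo_preprocessed` with `images` array
#'   `target x target x channels x N`, and `norm_min`/`norm_max` vectors.
#' @export
preprocess_stack <- function(stack, channels = 1, target = 64) {
  stopifnot(inherits(stack, "cryo_stack"))
  if (!channels %in% c(1, 3)) stop("channels must be 1 or 3")
  n <- dim(stack$images)[3]
  out <- array(0, dim = c(target, target, channels, n))
  nmin <- numeric(n); nmax <- numeric(n)
  for (i in seq_len(n)) {
    img <- downsample_image(stack$images[, , i], target)
    lo <- min(img); hi <- max(img)
    if (hi == lo) stop(sprintf("image %d is constant; cannot normalise", i))
    nmin[i] <- lo; nmax[i] <- hi
    img <- 2 * (img - lo) / (hi - lo) - 1
    for (c in seq_len(channels)) out[, , c, i] <- img
  }
  structure(list(images = out, channels = channels, target = target,
                 norm_min = nmin, norm_max = nmax,
                 labels_true = stack$labels_true),
            class = "cryo_preprocessed")
}

#' Invert the per-image normalisation of a preprocessed stack
#'
#' @param pre a `cryo_preprocessed`.
#' @param i image index.
#' @return The downsampled image on its original intensity scale.
#' @export
denormalize_image <- function(pre, i) {
  stopifnot(inherits(pre, "cryo_preprocessed"))
  img <- pre$images[, , 1, i]
  (img + 1) / 2 * (pre$norm_max[i] - pre$norm_min[i]) + pre$norm_min[i]
}
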