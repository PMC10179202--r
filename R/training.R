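#' Training configuration for the autoencoders
#'
#' Defaults follow the standard protocol for each model: the MLP autoencoder
#' is trained iteratively (500 epochs by default), the residual autoencoder
#' in one-pass mode (a single epoch); both use minibatch SGD with batch size
#' 32 and learning rate 0.001.
#'
#' @param kind `"mlp"` or `"res"`.
#' @param max_epochs training epochs; defaults to 500 (mlp) or 1 (res).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate SGD learning rate (default 0.001).
#' @param grad_clip global gradient-norm ceiling; occasional spiked
#'   minibatch gradients (an order of magnitude above the typical norm)
#'   would otherwise saturate the output Tanh and stall training.
#' @param seed integer seed controlling shuffling, initial weights and RReLU
#'   sampling.
#' @return A list of class `cryo_trainconfig`.
#' @export
training_config <- function(kind = c("mlp", "res"), max_epochs = NULL,
                            batch_size = 32, learning_rate = 0.001,
                            grad_clip = 500, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(max_epochs)) max_epochs <- if (kind == "mlp") 500L else 1L
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (grad_clip <= 0) stop("grad_clip must be positive")
  structure(list(kind = kind, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = "sgd",
                 grad_clip = grad_clip,
                 seed = as.integer(seed)), class = "cryo_trainconfig")
}

# rescale all gradients so their global L2 norm is at most `clip`
clip_gradients <- function(grads, clip) {
  total <- sum(vapply(grads, function(g) {
    if (!is.null(g$W)) sum(g$W^2) + sum(g$b^2)
    else sum(vapply(g, function(q) sum(unlist(q)^2), numeric(1)))
  }, numeric(1)))
  gn <- sqrt(total)
  if (gn <= clip) return(grads)
  scale <- clip / gn
  rapply(grads, function(x) x * scale, classes = "ANY", how = "replace")
}

#' Train an autoencoder by minibatch stochastic gradient descent
#'
#' Minimises the mean-squared reconstruction error by backpropagation. Data
#' order is reshuffled from the run seed each epoch (one-pass training
#' shuffles once). The per-epoch mean loss is recorded in `loss_history`.
#' Deterministic given `cfg$seed`.
#'
#' @param model a `cryo_ae` from [build_ae_mlp()] or [build_ae_res()].
#' @param data a `cryo_preprocessed` stack whose channel count matches the
#'   model (1 for mlp, 3 for res).
#' @param cfg a [training_config()]; must match the model kind.
#' @return The trained model (updated weights, `loss_history`,
#'   `trained = TRUE`).
#' @export
train_autoencoder <- function(model, data, cfg = training_config(model$kind)) {
  stopifnot(inherits(model, "cryo_ae"), inherits(data, "cryo_preprocessed"))
  if (cfg$kind != model$kind) stop("training config kind does not match model")
  if (data$channels != model$channels)
    stop(sprintf("model expects %d-channel input, data has %d channels",
                 model$channels, data$channels))
  N <- dim(data$images)[4]
  if (N < 1) stop("empty stack")
  mlp <- model$kind == "mlp"
  X <- if (mlp) t(matrix(data$images, nrow = 4096, ncol = N)) else NULL
  params <- model$params
  history <- numeric(cfg$max_epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(N)
      starts <- seq(1, N, by = cfg$batch_size)
      tot <- 0
      for (s in starts) {
        batch <- perm[s:min(s + cfg$batch_size - 1, N)]
        if (mlp) {
          out <- mlp_pass(params, X[batch, , drop = FALSE])
        } else {
          out <- res_pass(params, data$images[, , , batch, drop = FALSE],
                          training = TRUE)
          params <- out$p   # batch-norm running stats
        }
        params <- sgd_update(params, clip_gradients(out$grads, cfg$grad_clip),
                             cfg$learning_rate)
        tot <- tot + out$loss * length(batch)
      }
      history[epoch] <- tot / N
    }
  })
  model$params <- params
  model$loss_history <- history
  model$trained <- TRUE
  model$train_config <- cfg
  model
}

#' Save or load an autoencoder checkpoint
#'
#' A checkpoint is a single serialized container holding the architecture
#' descriptor, the weights and the training configuration; it can be
#' reloaded in a later session and used with [extract_latents()].
#'
#' @param model a `cryo_ae`.
#' @param path checkpoint path (RDS).
#' @return `save_ae_model` returns `path` invisibly; `load_ae_model` the
#'   restored model.
#' @export
save_ae_model <- function(model, path) {
  stopifnot(inherits(model, "cryo_ae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ae_model
#' @export
load_ae_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cryo_ae")) stop("not an autoencoder checkpoint")
  model
}

#' Encode a preprocessed stack into latent variables
#'
#' Applies the encoder in evaluation mode (fixed RReLU slope, frozen
#' batch-norm running statistics): a pure function of the weights and the
#' input, so duplicate images map to identical latent rows.
#'
#' @param model a `cryo_ae` (normally trained; untrained encoders are
#'   permitted for ablation studies).
#' @param data a `cryo_preprocessed` with the channel count the model
#'   expects.
#' @param batch evaluation chunk size (memory knob, no effect on values).
#' @return `N x latent_dim` numeric matrix, rows in stack order.
#' @export
extract_latents <- function(model, data, batch = 64L) {
  stopifnot(inherits(model, "cryo_ae"), inherits(data, "cryo_preprocessed"))
  if (data$channels != model$channels)
    stop(sprintf("model expects %d-channel input, data has %d channels",
                 model$channels, data$channels))
  N <- dim(data$images)[4]
  if (model$kind == "mlp") {
    X <- t(matrix(data$images, nrow = 4096, ncol = N))
    p <- model$params
    H1 <- pmax(sweep(X %*% p$enc1$W, 2, p$enc1$b, `+`), 0)
    Z <- sweep(H1 %*% p$enc2$W, 2, p$enc2$b, `+`)
    return(Z)
  }
  Z <- matrix(0, N, model$latent_dim)
  for (s in seq(1, N, by = batch)) {
    idx <- s:min(s + batch - 1, N)
    Z[idx, ] <- res_encode(model$params, data$images[, , , idx, drop = FALSE])
  }
  Z
}

#' Reconstruct images through a trained autoencoder
#'
#' Full encoder/decoder evaluation pass; used to inspect reconstruction
#' quality and compute held-out losses.
#'
#' @param model a `cryo_ae`.
#' @param data a matching `cryo_preprocessed`.
#' @return List with `images` (same shape as `data$images`) and `loss`.
#' @export
ae_reconstruct <- function(model, data) {
  stopifnot(inherits(model, "cryo_ae"), inherits(data, "cryo_preprocessed"))
  N <- dim(data$images)[4]
  if (model$kind == "mlp") {
    X <- t(matrix(data$images, nrow = 4096, ncol = N))
    out <- mlp_pass(model$params, X, want_grads = FALSE)
    imgs <- array(t(out$Y), dim = dim(data$images))
    return(list(images = imgs, loss = out$loss))
  }
  out <- res_pass(model$params, data$images, training = FALSE,
                  want_grads = FALSE)
  list(images = out$Y, loss = out$loss)
}
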