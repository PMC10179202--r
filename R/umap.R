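# Compact UMAP: exact k-nearest neighbours, smooth-kNN kernel calibration,
# fuzzy set union, spectral initialisation and negative-sampling SGD layout
# (compiled). Suited to the stack sizes this package works at (N up to a few
# thousand), where exact neighbour search and dense eigendecompositions are
# cheap.

# per-point kernel bandwidth: solve sum_j exp(-(d_ij - rho_i)/sigma) = log2(k)
smooth_knn_sigma <- function(d, rho, target, iters = 64) {
  lo <- 0; hi <- Inf; sigma <- 1
  for (it in seq_len(iters)) {
    val <- sum(exp(-pmax(0, d - rho) / sigma))
    if (abs(val - target) < 1e-5) break
    if (val > target) {
      hi <- sigma; sigma <- (lo + hi) / 2
    } else {
      lo <- sigma
      sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2
    }
  }
  sigma
}

# fit the rational output kernel 1/(1 + a d^(2b)) to the target curve
# exp(-(d - min_dist)) (1 for d < min_dist)
umap_ab_params <- function(min_dist, spread = 1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- nls(yv ~ 1 / (1 + a * xv^(2 * b)), start = list(a = 1.5, b = 1),
             control = list(maxiter = 200, warnOnly = TRUE))
  as.list(coef(fit))
}

#' Reduce latent variables to a 2D embedding with UMAP
#'
#' Builds the fuzzy simplicial graph of the latent vectors (exact Euclidean
#' kNN, locally adaptive exponential kernel with the standard smooth-kNN
#' calibration, fuzzy union symmetrisation) and optimises a 2D layout by
#' stochastic gradient descent with negative sampling. Also applicable to
#' flattened raw images, which is the "original images" baseline the
#' classification accuracy is compared against.
#'
#' @param latents `N x d` numeric matrix (N >= 10), or a
#'   `cryo_preprocessed` whose images are flattened.
#' @param seed integer seed; the same seed gives an identical embedding.
#' @param n_neighbors local neighbourhood size (default 15).
#' @param min_dist minimum separation in the embedding (default 0.1).
#' @param n_epochs layout optimisation epochs (default 300).
#' @return An object of class `cryo_embedding`: `points` (`N x 2`) plus the
#'   parameters used.
#' @export
reduce_umap_2d <- function(latents, seed = 1, n_neighbors = 15,
                           min_dist = 0.1, n_epochs = 300) {
  if (inherits(latents, "cryo_preprocessed")) {
    n <- dim(latents$images)[4]
    latents <- t(matrix(latents$images[, , 1, ],
                        nrow = prod(dim(latents$images)[1:2]), ncol = n))
  }
  latents <- as.matrix(latents)
  N <- nrow(latents)
  if (N < 10) stop("need at least 10 points")
  if (!all(is.finite(latents))) stop("latents contain non-finite values")
  k <- min(n_neighbors, N - 1)

  # exact kNN from the full distance matrix
  sq <- rowSums(latents^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(latents)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  diag(dm) <- Inf
  knn_idx <- t(apply(dm, 1, function(r) order(r)[seq_len(k)]))
  knn_d <- t(vapply(seq_len(N), function(i) dm[i, knn_idx[i, ]],
                    numeric(k)))

  # local fuzzy memberships
  rho <- knn_d[, 1]
  target <- log2(k)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    sigma <- smooth_knn_sigma(knn_d[i, ], rho[i], target)
    W[i, knn_idx[i, ]] <- exp(-pmax(0, knn_d[i, ] - rho[i]) / sigma)
  }
  P <- W + t(W) - W * t(W)   # fuzzy union

  ab <- umap_ab_params(min_dist)

  # spectral initialisation from the symmetric normalised graph Laplacian
  deg <- pmax(rowSums(P), 1e-12)
  Dm <- 1 / sqrt(deg)
  Lsym <- diag(N) - (P * Dm) %*% diag(Dm)
  eg <- eigen(Lsym, symmetric = TRUE)
  init <- eg$vectors[, c(N - 1, N - 2)]
  init <- init / max(abs(init)) * 10
  init <- init + with_seed(derive_seed(seed, "umap-jitter"),
                           matrix(rnorm(2 * N, sd = 1e-4), N, 2))

  edges <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  pts <- .umap_layout_cpp(init, edges[, 1] - 1L, edges[, 2] - 1L,
                          P[edges], as.integer(n_epochs), ab$a, ab$b,
                          1.0, 5L, derive_seed(seed, "umap-sgd"))
  structure(list(points = pts, n_neighbors = n_neighbors,
                 min_dist = min_dist, n_epochs = n_epochs, seed = seed,
                 a = ab$a, b = ab$b),
            class = "cryo_embedding")
}

#' @export
print.cryo_embedding <- function(x, ...) {
  cat(sprintf("<cryo_embedding> %d points, n_neighbors=%d, min_dist=%g\n",
              nrow(x$points), x$n_neighbors, x$min_dist))
  invisible(x)
}
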