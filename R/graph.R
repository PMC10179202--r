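#' Adaptive neighbourhood size for the SNN graph
#'
#' The empirical rule `k = floor(sqrt(N)) + NS`: the number of nearest
#' neighbours grows with the square root of the stack size, offset by the
#' shared-neighbour threshold.
#'
#' @param N total number of points (projection images).
#' @param NS shared-neighbour threshold (default 5).
#' @return Integer k.
#' @export
#' @examples
#' adaptive_k(1500)  # 43
#' adaptive_k(2000)  # 49
adaptive_k <- function(N, NS = 5) {
  if (N < 1 || NS < 0) stop("need N >= 1 and NS >= 0")
  as.integer(floor(sqrt(N)) + NS)
}

#' Euclidean k-nearest-neighbour sets
#'
#' For each point, the indices of its k nearest neighbours by Euclidean
#' distance, self excluded, distance ties broken towards the smaller index.
#'
#' @param points `N x d` numeric matrix or a `cryo_embedding`.
#' @param k neighbourhood size, `k < N`.
#' @return `N x k` integer matrix; row i holds the neighbour set of point i
#'   in increasing-distance order.
#' @export
knn_sets <- function(points, k) {
  if (inherits(points, "cryo_embedding")) points <- points$points
  points <- as.matrix(points)
  N <- nrow(points)
  if (k >= N) stop("k must be smaller than the number of points")
  sq <- rowSums(points^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  t(vapply(seq_len(N), function(i) {
    ord <- order(d2[i, ], seq_len(N))  # ties -> smaller index first
    ord[seq_len(k)]
  }, integer(k)))
}

#' Shared-nearest-neighbour adjacency
#'
#' Counts, for every pair (i, j), the overlap of their k-nearest-neighbour
#' sets, and connects the pair when the count strictly exceeds the
#' threshold `NS`. The result is the binary graph handed to the spectral
#' clustering step.
#'
#' @param knn `N x k` integer neighbour matrix from [knn_sets()].
#' @param NS shared-neighbour threshold (default 5); the adjacency rule is
#'   `MSNN(i, j) > NS`, strict.
#' @param points optional coordinates stored with the graph (used for the
#'   isolated-vertex repair during clustering).
#' @return An object of class `cryo_snn_graph` with `k`, `NS`, `knn`,
#'   `snn_counts` (symmetric integer matrix) and `adjacency` (binary,
#'   symmetric, zero diagonal).
#' @export
snn_adjacency <- function(knn, NS = 5, points = NULL) {
  knn <- as.matrix(knn)
  N <- nrow(knn)
  k <- ncol(knn)
  # membership matrix: B[i, j] = 1 iff j is a kNN of i; overlap = B B^T
  B <- matrix(0L, N, N)
  B[cbind(rep(seq_len(N), k), as.vector(knn))] <- 1L
  counts <- tcrossprod(B)
  storage.mode(counts) <- "integer"
  diag(counts) <- 0L
  adj <- (counts > NS) * 1L
  diag(adj) <- 0L
  structure(list(k = k, NS = NS, knn = knn, snn_counts = counts,
                 adjacency = adj, points = points),
            class = "cryo_snn_graph")
}

#' @export
print.cryo_snn_graph <- function(x, ...) {
  cat(sprintf("<cryo_snn_graph> %d vertices, k=%d, NS=%d, %d edges\n",
              nrow(x$adjacency), x$k, x$NS, sum(x$adjacency) / 2))
  invisible(x)
}

#' Build the SNN graph of a 2D embedding
#'
#' Convenience wrapper: chooses k adaptively from the number of points
#' ([adaptive_k()]), computes the kNN sets and the shared-neighbour
#' adjacency.
#'
#' @param embedding a `cryo_embedding` or `N x 2` matrix.
#' @param NS shared-neighbour threshold (default 5).
#' @param k neighbourhood size; defaults to `adaptive_k(N, NS)`.
#' @return A `cryo_snn_graph`.
#' @export
build_snn_graph <- function(embedding, NS = 5, k = NULL) {
  pts <- if (inherits(embedding, "cryo_embedding")) embedding$points
         else as.matrix(embedding)
  if (is.null(k)) k <- adaptive_k(nrow(pts), NS)
  snn_adjacency(knn_sets(pts, k), NS = NS, points = pts)
}

# connected components of a binary adjacency matrix (BFS)
graph_components <- function(adj) {
  N <- nrow(adj)
  comp <- integer(N)
  cur <- 0L
  for (s in seq_len(N)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
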