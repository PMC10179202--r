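#' Normalized spectral clustering of an SNN graph
#'
#' Partitions the binary shared-nearest-neighbour adjacency into K groups
#' with the symmetric-normalised-Laplacian algorithm: take the K leading
#' eigenvectors of `D^-1/2 A D^-1/2`, normalise the rows of the spectral
#' embedding to unit length, and run seeded k-means (10 restarts) on the
#' rows. Isolated vertices (degree 0) are first repaired by connecting each
#' to its nearest neighbour in the stored 2D coordinates so the Laplacian is
#' well posed; repairs are reported in the diagnostics. When the repaired
#' graph still has more connected components than K the leading eigenspace
#' is a degenerate span of component indicators, so components are merged
#' into K groups by single-linkage over the embedding coordinates instead
#' of an arbitrary k-means tie-break; the merge is flagged in the
#' diagnostics.
#'
#' @param graph a `cryo_snn_graph` (or a plain binary adjacency matrix).
#' @param K number of clusters (K >= 1, at most N).
#' @param seed integer seed for the k-means step.
#' @return An object of class `cryo_clusters`: `labels` (0-based integers),
#'   `K`, and `diagnostics` (eigenvalues, number of connected components,
#'   repaired vertices, k-means convergence).
#' @export
spectral_cluster <- function(graph, K, seed = 1) {
  if (inherits(graph, "cryo_snn_graph")) {
    A <- graph$adjacency
    pts <- graph$points
  } else {
    A <- as.matrix(graph)
    pts <- NULL
  }
  N <- nrow(A)
  if (K < 1 || K > N) stop("K must be between 1 and N")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")

  repaired <- integer(0)
  deg <- rowSums(A)
  if (any(deg == 0)) {
    iso <- which(deg == 0)
    if (is.null(pts)) {
      # no coordinates: attach isolated vertices to the first vertex
      for (i in iso) {
        j <- if (i == 1) 2L else 1L
        A[i, j] <- A[j, i] <- 1
      }
    } else {
      sq <- rowSums(pts^2)
      for (i in iso) {
        d2 <- sq + sq[i] - 2 * drop(pts %*% pts[i, ])
        d2[i] <- Inf
        j <- which.min(d2)
        A[i, j] <- A[j, i] <- 1
      }
    }
    repaired <- iso
    deg <- rowSums(A)
  }

  comp <- graph_components(A)
  ncomp <- max(comp)
  merged <- FALSE
  if (ncomp > K && !is.null(pts)) {
    # more components than clusters: the leading eigenspace is spanned by
    # the component indicators and carries no between-component affinity,
    # so k-means on it would merge components arbitrarily. Merge instead by
    # agglomeration over component centroid distances in the embedding
    # (deterministic and robust to stray boundary points).
    merged <- TRUE
    cent <- t(vapply(seq_len(ncomp), function(a)
      colMeans(pts[comp == a, , drop = FALSE]), numeric(ncol(pts))))
    hc <- stats::hclust(stats::dist(cent), method = "single")
    grp <- stats::cutree(hc, k = K)
    labels <- grp[comp] - 1L
    diag_info <- list(eigenvalues = NULL, eigengap = NA_real_,
                      n_components = ncomp, repaired_vertices = repaired,
                      component_merge = TRUE,
                      warning = sprintf(
                        "graph has %d connected components for K = %d; merged by single linkage",
                        ncomp, K))
    return(structure(list(labels = as.integer(labels), K = as.integer(K),
                          diagnostics = diag_info),
                     class = "cryo_clusters"))
  }

  isq <- 1 / sqrt(deg)
  M <- A * (isq %o% isq)          # D^-1/2 A D^-1/2
  eg <- eigen(M, symmetric = TRUE)
  U <- eg$vectors[, seq_len(K), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn

  km <- with_seed(derive_seed(seed, "spectral-kmeans"), {
    tryCatch(kmeans(U, centers = K, nstart = 10, iter.max = 200),
             error = function(e)
               # duplicate rows can abort Hartigan-Wong; Lloyd is robust
               kmeans(U, centers = K, nstart = 30, iter.max = 200,
                      algorithm = "Lloyd"))
  })
  diag_info <- list(eigenvalues = eg$values[seq_len(min(N, K + 5))],
                    eigengap = if (K < N) eg$values[K] - eg$values[K + 1] else NA_real_,
                    n_components = ncomp,
                    repaired_vertices = repaired,
                    component_merge = merged,
                    kmeans_iterations = km$iter)
  if (ncomp > K)
    diag_info$warning <- sprintf(
      "graph has %d connected components but K = %d; clusters merge components",
      ncomp, K)
  structure(list(labels = km$cluster - 1L, K = as.integer(K),
                 diagnostics = diag_info),
            class = "cryo_clusters")
}

#' @export
print.cryo_clusters <- function(x, ...) {
  cat(sprintf("<cryo_clusters> K=%d, sizes: %s\n", x$K,
              paste(tabulate(x$labels + 1L, nbins = x$K), collapse = ", ")))
  invisible(x)
}
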