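test_that("adaptive k follows floor(sqrt(N)) + NS", {
  expect_identical(adaptive_k(1500, 5), 43L)
  expect_identical(adaptive_k(2000, 5), 49L)
  expect_identical(adaptive_k(100, 0), 10L)
  expect_error(adaptive_k(0, 5), "N")
})

test_that("kNN sets match hand geometry and a brute-force oracle", {
  pts <- matrix(c(0, 1, 10, 0, 0, 0), ncol = 2)
  knn <- knn_sets(pts, 1)
  expect_identical(as.vector(knn), c(2L, 1L, 2L))
  set.seed(4)
  for (trial in 1:5) {
    p <- matrix(rnorm(100), ncol = 2)
    k <- 7
    got <- knn_sets(p, k)
    d <- as.matrix(dist(p))
    diag(d) <- Inf
    for (i in seq_len(nrow(p))) {
      oracle <- order(d[i, ], seq_len(nrow(p)))[1:k]
      expect_identical(sort(got[i, ]), sort(oracle))
    }
    expect_true(all(rowSums(got == seq_len(nrow(p))) == 0))  # no self
  }
})

test_that("SNN counts and adjacency follow the set-intersection rule", {
  knn <- rbind(c(2L, 3L, 4L), c(3L, 4L, 5L), c(1L, 2L, 5L), c(1L, 2L, 3L),
               c(1L, 2L, 4L))
  g <- snn_adjacency(knn, NS = 1)
  expect_identical(g$snn_counts[1, 2], 2L)  # {3,4}
  expect_identical(g$adjacency[1, 2], 1L)
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  # identical kNN sets overlap fully
  same <- rbind(c(2L, 3L), c(3L, 4L), c(2L, 4L), c(2L, 3L))
  expect_identical(snn_adjacency(same, NS = 0)$snn_counts[1, 4], 2L)
})

test_that("SNN graph equals the brute-force oracle on random point sets", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(20:60, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    k <- adaptive_k(n, 3)
    g <- build_snn_graph(pts, NS = 3, k = k)
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    sets <- lapply(seq_len(n), function(i) order(d[i, ], seq_len(n))[1:k])
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cnt <- length(intersect(sets[[i]], sets[[j]]))
      expect_identical(g$snn_counts[i, j], as.integer(cnt))
      expect_identical(g$adjacency[i, j], as.integer(cnt > 3))
    }
    expect_true(all(g$snn_counts <= k))
  }
})

test_that("permuting points permutes the SNN graph identically", {
  set.seed(12)
  pts <- matrix(rnorm(80), ncol = 2)
  g <- build_snn_graph(pts, NS = 2, k = 6)
  perm <- sample(nrow(pts))
  g2 <- build_snn_graph(pts[perm, ], NS = 2, k = 6)
  expect_identical(g2$adjacency, g$adjacency[perm, perm])
  expect_identical(g2$snn_counts, g$snn_counts[perm, perm])
})

test_that("spectral clustering recovers planted structure", {
  # two disjoint 10-cliques
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 1; A[11:20, 11:20] <- 1; diag(A) <- 0
  cl <- spectral_cluster(A, 2, seed = 1)
  expect_equal(match_labels_accuracy(cl, rep(0:1, each = 10))$overall, 1)
  # single clique, K = 1
  B <- matrix(1, 8, 8); diag(B) <- 0
  expect_true(all(spectral_cluster(B, 1, seed = 1)$labels == 0L))
  # seeded planted 3-block partition
  set.seed(7)
  n <- 90; blocks <- rep(0:2, each = 30)
  P <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) 0.9 else 0.02
    P[i, j] <- P[j, i] <- rbinom(1, 1, p)
  }
  cl3 <- spectral_cluster(P, 3, seed = 1)
  expect_gte(match_labels_accuracy(cl3, blocks)$overall, 0.95)
  expect_identical(spectral_cluster(P, 3, seed = 1)$labels, cl3$labels)
})

test_that("isolated vertices are repaired and reported", {
  A <- matrix(0, 12, 12)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  pts <- rbind(matrix(rnorm(10, 0), ncol = 2),
               matrix(rnorm(10, 5), ncol = 2),
               c(0.1, 0.1), c(5.1, 5.1))
  cl <- spectral_cluster(structure(list(adjacency = A, points = pts),
                                   class = "cryo_snn_graph"), 2, seed = 1)
  expect_identical(sort(cl$diagnostics$repaired_vertices), c(11L, 12L))
  expect_identical(length(unique(cl$labels)), 2L)
})

test_that("component merging handles more fragments than clusters", {
  # four tight clumps in 2D, K = 2: nearest clumps must merge
  set.seed(5)
  pts <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
               matrix(rnorm(40, 1, 0.1), ncol = 2),
               matrix(rnorm(40, 10, 0.1), ncol = 2),
               matrix(rnorm(40, 11, 0.1), ncol = 2))
  g <- build_snn_graph(pts, NS = 3, k = 8)
  cl <- spectral_cluster(g, 2, seed = 1)
  truth <- rep(0:1, each = 40)
  expect_equal(match_labels_accuracy(cl, truth)$overall, 1)
  expect_true(isTRUE(cl$diagnostics$component_merge))
})
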