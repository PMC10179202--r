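test_that("phantom volumes are deterministic, nonnegative and class-distinct", {
  v1 <- make_phantom_volume(0, 64, num_blobs = 5, separation = 0.5, seed = 7)
  v1b <- make_phantom_volume(0, 64, num_blobs = 5, separation = 0.5, seed = 7)
  expect_identical(v1$grid, v1b$grid)
  expect_true(all(v1$grid >= 0))
  v2 <- make_phantom_volume(1, 64, num_blobs = 5, separation = 0.5, seed = 7)
  expect_lt(volume_ncc(v1, v2), 0.9)
  expect_identical(max(abs(make_phantom_volume(0, 64, num_blobs = 0)$grid)), 0)
  expect_error(make_phantom_volume(0, 16), "size")
})

test_that("uniform orientation sampling yields proper, Haar-like rotations", {
  rots <- sample_orientations_uniform(200, seed = 3)
  for (R in rots[1:20]) {
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_lt(abs(det(R) - 1), 1e-10)
  }
  expect_identical(rots, sample_orientations_uniform(200, seed = 3))
  # Haar measure has zero-mean matrix entries
  big <- sample_orientations_uniform(10000, seed = 11)
  m <- Reduce(`+`, big) / length(big)
  expect_lt(max(abs(m)), 0.02)
})

test_that("ZYZ Euler conversion round-trips", {
  for (R in sample_orientations_uniform(25, seed = 9)) {
    ang <- matrix_to_euler(R)
    expect_lt(max(abs(euler_to_matrix(ang[1], ang[2], ang[3]) - R)), 1e-10)
  }
})

test_that("projection conserves mass, is linear, and respects symmetry", {
  v <- make_phantom_volume(0, 48, num_blobs = 6, seed = 5)
  id <- diag(3)
  p <- project_volume(v, id, 48)
  expect_lt(abs(sum(p) - sum(v$grid)) / sum(v$grid), 0.005)
  # zero volume projects to zero
  z <- new_volume(array(0, dim = c(48, 48, 48)))
  expect_identical(max(abs(project_volume(z, id, 48))), 0)
  # linearity at fixed orientation
  v2 <- make_phantom_volume(1, 48, num_blobs = 6, seed = 5)
  R <- sample_orientations_uniform(1, seed = 2)[[1]]
  pa <- project_volume(v, R, 48)
  pb <- project_volume(v2, R, 48)
  vc <- new_volume(2 * v$grid + 3 * v2$grid)
  pc <- project_volume(vc, R, 48)
  expect_lt(max(abs(pc - 2 * pa - 3 * pb)) / max(abs(pc)), 1e-6)
  # spherically symmetric volume: projections agree across orientations
  s <- make_sphere_volume(48)
  rr <- sample_orientations_uniform(2, seed = 8)
  q1 <- project_volume(s, rr[[1]], 48)
  q2 <- project_volume(s, rr[[2]], 48)
  expect_lt(sqrt(mean((q1 - q2)^2)) / sd(q1), 1e-2)
  expect_error(project_volume(v, id, 64), "out_size")
})

test_that("SNR noise model matches the variance-ratio definition", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64, sd = 2), 64)  # pixel variance ~4
  noisy <- add_noise_snr(img, snr = 0.1)
  # noise variance should be var(img)/0.1
  expect_lt(abs(var(as.vector(noisy - img)) / (var(as.vector(img)) / 0.1) - 1),
            0.1)
  # snr -> infinity leaves the image untouched
  quiet <- add_noise_snr(img, snr = 1e12)
  expect_lt(max(abs(quiet - img)), 1e-4 * sd(img))
  # empirical 1/snr over a larger image
  big <- matrix(rnorm(256 * 256), 256)
  ns <- add_noise_snr(big, snr = 0.25)
  expect_lt(abs(var(as.vector(ns - big)) / var(as.vector(big)) - 4) / 4, 0.05)
  expect_error(add_noise_snr(matrix(1, 8, 8), 0.1), "variance")
  expect_error(add_noise_snr(img, -1), "snr")
})

test_that("estimate_snr recovers the generating SNR and its invariances", {
  set.seed(2)
  clean <- matrix(rnorm(64 * 64), 64)
  noisy <- add_noise_snr(clean, snr = 0.1)
  expect_lt(abs(estimate_snr(clean, noisy) - 0.1) / 0.1, 0.10)
  # zero signal
  expect_identical(estimate_snr(matrix(0, 16, 16),
                                matrix(rnorm(256), 16)), 0)
  # scale invariance
  expect_equal(estimate_snr(3 * clean, 3 * noisy),
               estimate_snr(clean, noisy))
  expect_identical(estimate_snr(clean, clean), Inf)
})

test_that("heterogeneous stacks have the stated size, labels and determinism", {
  stack <- make_tiny_stack(K = 3, per_class = 4, size = 32)
  expect_identical(dim(stack$images), c(32L, 32L, 12L))
  expect_identical(as.integer(table(stack$labels_true)), c(4L, 4L, 4L))
  expect_true(all(stack$labels_true %in% 0:2))
  expect_length(stack$orientations, 12)
  stack2 <- make_tiny_stack(K = 3, per_class = 4, size = 32)
  expect_identical(stack$images, stack2$images)
  vols <- list(make_phantom_volume(0, 32, seed = 1),
               make_phantom_volume(1, 48, seed = 1))
  cfg <- simulation_config(num_classes = 2, images_per_class = 2)
  expect_error(build_heterogeneous_stack(vols, cfg), "dimension")
})

test_that("per-image noise follows the clean projection variance", {
  # over replicates, the recovered SNR matches the configured one
  vols <- lapply(0:1, function(c) make_phantom_volume(c, 32, seed = 3))
  cfg <- simulation_config(2, 20, snr = 0.2, seed = 9)
  stack <- build_heterogeneous_stack(vols, cfg)
  ors <- stack$orientations
  snrs <- vapply(seq_len(40), function(i) {
    k <- stack$labels_true[i] + 1L
    clean <- project_volume(vols[[k]], ors[[i]], 32)
    estimate_snr(clean, stack$images[, , i])
  }, numeric(1))
  se <- sd(snrs) / sqrt(length(snrs))
  expect_lt(abs(mean(snrs) - 0.2), 2 * se + 0.02)
})
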