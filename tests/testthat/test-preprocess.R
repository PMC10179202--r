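test_that("Fourier-crop downsampling preserves DC and removes noise energy", {
  expect_equal(downsample_image(matrix(3.5, 128, 128), 64),
               matrix(3.5, 64, 64), tolerance = 1e-12)
  img <- matrix(rnorm(64 * 64), 64)
  expect_identical(downsample_image(img, 64), img)
  big <- matrix(rnorm(320 * 320), 320)
  small <- downsample_image(big, 64)
  expect_lt(var(as.vector(small)), var(as.vector(big)))
  expect_error(downsample_image(small, 128), "upsampling")
})

test_that("downsampling a smooth image approximates simple decimation", {
  ax <- seq(0, 2 * pi, length.out = 128)
  img <- outer(sin(2 * ax), cos(3 * ax))
  ds <- downsample_image(img, 64)
  expect_equal(mean(ds), mean(img), tolerance = 1e-10)
  expect_gt(cor(as.vector(ds), as.vector(img[seq(1, 128, 2), seq(1, 128, 2)])),
            0.99)
})

test_that("channel replication gives three identical channels", {
  img <- matrix(rnorm(64 * 64), 64)
  rep3 <- replicate_channels(img)
  expect_identical(dim(rep3), c(64L, 64L, 3L))
  expect_identical(rep3[, , 1], rep3[, , 2])
  expect_identical(rep3[, , 1], rep3[, , 3])
  expect_equal(sum(rep3), 3 * sum(img))
  expect_error(replicate_channels(rep3), "single-channel")
})

test_that("per-image normalisation maps to [-1, 1] and is invertible", {
  stack <- make_tiny_stack(K = 2, per_class = 3, size = 32)
  pre <- preprocess_stack(stack, channels = 1, target = 32)
  n <- dim(pre$images)[4]
  for (i in seq_len(n)) {
    expect_equal(min(pre$images[, , 1, i]), -1)
    expect_equal(max(pre$images[, , 1, i]), 1)
  }
  # {0, 5, 10} -> {-1, 0, 1}
  one <- new_particle_stack(array(c(0, 5, 10, 5), dim = c(2, 2, 1)))
  p1 <- preprocess_stack(one, channels = 1, target = 2)
  expect_equal(sort(unique(as.vector(p1$images))), c(-1, 0, 1))
  # inverse mapping recovers the downsampled image
  raw <- downsample_image(stack$images[, , 2], 32)
  expect_equal(denormalize_image(pre, 2), raw, tolerance = 1e-12)
  const <- new_particle_stack(array(1, dim = c(4, 4, 1)))
  expect_error(preprocess_stack(const, channels = 1, target = 4), "constant")
})

test_that("preprocessing images is order-independent", {
  stack <- make_tiny_stack(K = 2, per_class = 4, size = 32)
  pre <- preprocess_stack(stack, channels = 1, target = 32)
  perm <- c(5, 1, 8, 2, 3, 7, 6, 4)
  shuffled <- new_particle_stack(stack$images[, , perm],
                                 labels_true = stack$labels_true[perm])
  pre2 <- preprocess_stack(shuffled, channels = 1, target = 32)
  expect_equal(pre2$images[, , 1, 1], pre$images[, , 1, 5])
  expect_equal(pre2$images[, , 1, 4], pre$images[, , 1, 2])
})
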