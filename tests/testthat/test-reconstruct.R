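test_that("FSC identities: self, sign flip, symmetry, scale invariance", {
  v <- make_phantom_volume(0, 32, num_blobs = 5, seed = 3)
  self <- fsc_curve(v, v)
  expect_true(all(abs(self$fsc - 1) < 1e-6))
  neg <- fsc_curve(v, new_volume(-v$grid))
  expect_true(all(abs(neg$fsc + 1) < 1e-6))
  w <- make_phantom_volume(1, 32, num_blobs = 5, seed = 3)
  expect_equal(fsc_curve(v, w)$fsc, fsc_curve(w, v)$fsc)
  expect_equal(fsc_curve(new_volume(2.5 * v$grid), w)$fsc,
               fsc_curve(v, w)$fsc, tolerance = 1e-12)
  expect_error(fsc_curve(v, make_phantom_volume(0, 48, seed = 3)),
               "dimensions")
})

test_that("independent noise volumes decorrelate across shells", {
  set.seed(6)
  n1 <- new_volume(array(rnorm(64^3), dim = c(64, 64, 64)))
  n2 <- new_volume(array(rnorm(64^3), dim = c(64, 64, 64)))
  fc <- fsc_curve(n1, n2)
  expect_lt(mean(abs(fc$fsc[fc$shell > 0])), 0.1)
})

test_that("resolution crossing is interpolated and bounded by Nyquist", {
  flat <- data.frame(shell = 0:16, freq = (0:16) / 32,
                     freq_invA = (0:16) / 32, fsc = rep(1, 17))
  expect_equal(resolution_at_threshold(flat, 0.5, voxel_size = 1.1), 2.2)
  step <- flat
  step$fsc <- c(rep(1, 9), rep(0, 8))  # drops after shell 8
  res <- resolution_at_threshold(step, 0.5, voxel_size = 1)
  expect_gt(res, 1 / (9 / 32))
  expect_lt(res, 1 / (8 / 32))
  # monotone curve: higher threshold -> worse (larger) resolution
  mono <- flat
  mono$fsc <- seq(1, 0, length.out = 17)
  expect_gte(resolution_at_threshold(mono, 0.8),
             resolution_at_threshold(mono, 0.3))
  expect_error(resolution_at_threshold(flat, 1.5), "threshold")
})

test_that("reconstruction reproduces a volume from its clean projections", {
  v <- make_sphere_volume(48)
  ors <- sample_orientations_uniform(250, seed = 4)
  imgs <- array(0, c(48, 48, 250))
  for (i in 1:250) imgs[, , i] <- project_volume(v, ors[[i]], 48)
  stack <- new_particle_stack(imgs, orientations = ors)
  rec <- backproject_reconstruct(stack)
  fc <- fsc_curve(rec, v)
  expect_gt(min(fc$fsc[fc$shell <= 12]), 0.9)
  expect_error(backproject_reconstruct(stack, integer(0)), "empty")
  no_or <- new_particle_stack(imgs)
  expect_error(backproject_reconstruct(no_or), "orientations")
})

test_that("projections of the zero volume reconstruct to zero", {
  z <- new_volume(array(0, dim = c(32, 32, 32)))
  ors <- sample_orientations_uniform(20, seed = 1)
  imgs <- array(0, c(32, 32, 20))
  stack <- new_particle_stack(imgs, orientations = ors)
  rec <- backproject_reconstruct(stack)
  expect_lt(max(abs(rec$grid)), 1e-10)
})

test_that("FSC curves write to CSV with resolution columns", {
  v <- make_phantom_volume(0, 32, seed = 2)
  fc <- fsc_curve(v, v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fsc_csv(fc, path)
  got <- read.csv(path)
  expect_identical(nrow(got), nrow(fc))
  expect_equal(got$fsc, fc$fsc, tolerance = 1e-12)
})
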