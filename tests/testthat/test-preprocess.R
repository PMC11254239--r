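test_that("bias correction leaves a bias-free constant phantom unchanged", {
  d <- c(16, 16, 12)
  vol <- array(100, d)
  mask <- array(0L, d); mask[5:12, 5:12, 4:9] <- 1L
  out <- correct_bias(vol, mask)
  expect_lt(max(abs(out - vol)) / 100, 1e-6)
})

test_that("bias correction recovers a smooth 20% multiplicative field", {
  d <- c(24, 24, 18)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  # smooth low-frequency field, 20% amplitude
  field <- exp(0.2 * array(sin(2 * pi * g$x / d[1]) * cos(2 * pi * g$y / d[2]) +
                           0.5 * sin(2 * pi * g$z / d[3]), d))
  vol <- 100 * field
  mask <- array(0L, d); mask[4:21, 4:21, 3:16] <- 1L
  out <- correct_bias(vol, mask, df = 6)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(vol[mask == 1]) / cv(out[mask == 1]), 5)
  expect_equal(mean(out[mask == 1]), mean(vol[mask == 1]), tolerance = 1e-10)
  # the correction ratio is spatially smooth
  ratio <- array(vol / out, d)
  grad <- abs(diff(ratio))          # voxel-to-voxel change along axis 1
  expect_lt(max(grad), 0.1)
})

test_that("non-positive voxels inside the mask are shifted with a warning", {
  d <- c(10, 10, 8)
  vol <- array(50, d); mask <- array(1L, d)
  vol[5, 5, 4] <- -1
  expect_warning(correct_bias(vol, mask), "non-positive")
})

test_that("z-score normalization has the closed-form behaviour", {
  v <- array(c(1, 2, 3), c(3, 1, 1))
  out <- zscore_normalize(v)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out), 1, tolerance = 1e-12)
  # idempotence
  expect_equal(zscore_normalize(out), out, tolerance = 1e-8)
  # constant volume errors, naming the sequence
  expect_error(zscore_normalize(array(5, c(3, 2, 2)), name = "DWI"), "DWI")
})

test_that("isotropic resampling: identity, constants and linear ramps", {
  d <- c(12, 10, 8)
  v <- array(rnorm(prod(d)), d)
  expect_equal(resample_isotropic(v, c(1, 1, 1), c(1, 1, 1)), v)
  out <- resample_isotropic(array(7, d), c(2, 2, 2), c(1, 1, 1))
  expect_equal(dim(out), d * 2)
  expect_true(all(abs(out - 7) < 1e-9))
  # ramp along axis 1, resampled 2mm -> 1mm
  ramp <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  rout <- resample_isotropic(ramp, c(2, 1, 1), c(1, 1, 1))
  expected <- 1 + (seq_len(dim(rout)[1]) - 1) * 0.5
  interior <- 3:(length(expected) - 3)
  expect_lt(max(abs(rout[interior, 1, 1] - expected[interior])), 1e-3)
  # labels use nearest neighbour and stay integral
  lab <- array(sample(0:3, prod(d), TRUE), d)
  lout <- resample_isotropic(lab, c(2, 2, 2), c(1, 1, 1), "nearest")
  expect_true(all(lout %in% 0:3))
  expect_error(resample_isotropic(array(0.5, d), c(1, 1, 1), c(2, 2, 2), "nearest"),
               "integer")
})

test_that("gray-level discretization maps range ends and handles degeneracy", {
  d <- c(8, 8, 6)
  mask <- array(1L, d)
  v <- array(runif(prod(d)), d)
  disc <- discretize_gray_levels(v, mask, 32)
  expect_equal(disc[which.min(v)], 1L)
  expect_equal(disc[which.max(v)], 32L)
  expect_true(all(disc >= 1 & disc <= 32))
  # uniform values occupy all 32 levels roughly evenly
  big <- array(runif(20000), c(50, 40, 10))
  db <- discretize_gray_levels(big, array(1L, dim(big)), 32)
  occ <- tabulate(db, 32)
  expect_equal(length(occ[occ > 0]), 32)
  expect_lt(max(occ) / min(occ), 1.5)
  # constant tumor: all level 1 with warning
  expect_warning(dc <- discretize_gray_levels(array(3, d), mask, 32), "constant")
  expect_true(all(dc == 1))
  # outside mask is 0
  m2 <- array(0L, d); m2[2:4, 2:4, 2:4] <- 1L
  d2 <- discretize_gray_levels(v, m2, 8)
  expect_true(all(d2[m2 == 0] == 0))
})

test_that("the preprocessing chain enforces its fixed order and contracts", {
  expect_error(preprocess_config(order = c("zscore", "bias", "resample",
                                           "discretize")), "fixed")
  res <- make_preprocessed(tiny_params(seed = 2))
  pre <- res$pre
  for (nm in SEQUENCE_NAMES) {
    expect_true(all(pre$discrete[[nm]][pre$tumor_mask == 0] == 0))
    expect_true(max(pre$discrete[[nm]]) <= pre$n_gray_levels)
    expect_equal(mean(pre$sequences[[nm]]), 0, tolerance = 1e-8)
  }
})
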