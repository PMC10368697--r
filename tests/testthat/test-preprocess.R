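test_that("clip_and_standardize yields mean 0 and sd 1", {
  set.seed(1)
  img <- image_volume(array(rexp(20^3, 0.01), c(20, 20, 20)), rep(0.3, 3))
  out <- clip_and_standardize(img)
  expect_lt(abs(mean(out$data)), 1e-6)
  expect_lt(abs(sd(out$data) - 1), 1e-6)
})

test_that("standardization is idempotent on an in-range standardized image", {
  set.seed(2)
  img <- image_volume(array(rnorm(16^3), c(16, 16, 16)), rep(0.3, 3))
  cfg <- preprocess_config(clip_percentiles = c(0, 100))
  once <- clip_and_standardize(img, cfg)
  twice <- clip_and_standardize(once, cfg)
  expect_lt(max(abs(twice$data - once$data)), 1e-6)
})

test_that("constant images are rejected", {
  img <- image_volume(array(5, c(8, 8, 8)), rep(1, 3))
  expect_error(clip_and_standardize(img), "constant")
})

test_that("percentile clipping matches a sort-based oracle on a ramp", {
  ramp <- array(0:999, c(10, 10, 10))
  img <- image_volume(ramp, rep(1, 3))
  out <- clip_and_standardize(img)
  # sort-based oracle with linear interpolation between order statistics
  # (type-7: h = (n - 1) * p + 1)
  v <- sort(as.vector(ramp))
  n <- length(v)
  q <- function(p) {
    h <- (n - 1) * p + 1
    fl <- floor(h)
    v[fl] + (h - fl) * (v[min(fl + 1, n)] - v[fl])
  }
  clipped <- pmin(pmax(as.vector(ramp), q(0.005)), q(0.995))
  expected <- (clipped - mean(clipped)) / sd(clipped)
  expect_lt(max(abs(as.vector(out$data) - expected)), 1e-10)
  # the clipped maximum corresponds to the 99.5th percentile of the oracle
  expect_equal(max(out$data),
               (q(0.995) - mean(clipped)) / sd(clipped), tolerance = 1e-10)
})

test_that("standardization preserves voxel ordering within the clipped range", {
  set.seed(3)
  img <- image_volume(array(runif(12^3, 0, 100), c(12, 12, 12)), rep(1, 3))
  out <- clip_and_standardize(img)
  i <- sample(12^3, 200)
  j <- sample(12^3, 200)
  inner <- img$data > quantile(img$data, 0.005) &
    img$data < quantile(img$data, 0.995)
  sel <- inner[i] & inner[j]
  expect_true(all(sign(out$data[i] - out$data[j])[sel] ==
                  sign(img$data[i] - img$data[j])[sel]))
})

test_that("bias correction leaves an unbiased phantom essentially unchanged", {
  ph <- quick_phantom(seed = 4, noise = 0, bias = 0)
  out <- correct_bias(ph$image, ph$vessel_mask)
  rel <- abs(out$data - ph$image$data) / ph$image$data
  expect_lt(max(rel[ph$vessel_mask$data]), 0.02)
})

test_that("bias correction reduces within-vessel coefficient of variation", {
  ph <- quick_phantom(seed = 5, noise = 0, bias = 0.3)
  cv <- function(x) sd(x) / mean(x)
  before <- cv(ph$image$data[ph$vessel_mask$data])
  out <- correct_bias(ph$image, ph$vessel_mask)
  after <- cv(out$data[ph$vessel_mask$data])
  expect_lt(after, before)
})

test_that("a known smooth field on a constant image is recovered within 5%", {
  d <- c(24, 24, 24)
  gx <- rep(seq(-1, 1, length.out = d[1]), times = d[2] * d[3])
  gy <- rep(rep(seq(-1, 1, length.out = d[2]), each = d[1]), times = d[3])
  gz <- rep(seq(-1, 1, length.out = d[3]), each = d[1] * d[2])
  field <- array(exp(0.2 * gx - 0.15 * gy^2 + 0.1 * gx * gz), d)
  img <- image_volume(100 * field, rep(1, 3))
  mask <- binary_mask(array(TRUE, d), rep(1, 3))
  out <- correct_bias(img, mask)
  expect_lt(diff(range(out$data)) / mean(out$data), 0.05)
})

test_that("degenerate masks are passed through with a warning", {
  ph <- quick_phantom(seed = 6, shape = c(24, 24, 24))
  tiny <- binary_mask(array(FALSE, dim(ph$image$data)), ph$image$spacing)
  tiny$data[1:3, 1, 1] <- TRUE
  expect_warning(out <- correct_bias(ph$image, tiny), "fewer than 100")
  expect_identical(out$data, ph$image$data)
})

test_that("resampling preserves spacing, extent and mask binarity", {
  set.seed(7)
  img <- image_volume(array(rnorm(64^3), c(64, 64, 64)), rep(0.3, 3))
  expect_identical(dim(resample_isotropic(img, c(0.3, 0.3, 0.3))$data),
                   dim(img$data))
  coarse <- image_volume(array(rnorm(64^3), c(64, 64, 64)), rep(0.6, 3))
  fine <- resample_isotropic(coarse, c(0.3, 0.3, 0.3))
  expect_true(all(abs(dim(fine$data) - 128) <= 1))
  expect_identical(fine$spacing, c(0.3, 0.3, 0.3))
  m <- binary_mask(random_blob_mask(8, c(30, 30, 30)), rep(0.5, 3))
  rm <- resample_isotropic(m, c(0.3, 0.3, 0.3))
  expect_true(is.logical(rm$data))
  expect_true(all(rm$data %in% c(TRUE, FALSE)))
  # anisotropic input becomes isotropic with preserved physical extent
  an <- image_volume(array(rnorm(32 * 32 * 16), c(32, 32, 16)),
                     c(0.35, 0.35, 0.7))
  iso <- resample_isotropic(an, rep(0.35, 3))
  expect_equal(dim(iso$data)[3] * 0.35, 16 * 0.7, tolerance = 0.35)
})

test_that("the full preprocessing pipeline is deterministic", {
  ph <- quick_phantom(seed = 9, noise = 10, bias = 0.2)
  cfg <- preprocess_config()
  a <- preprocess_volume(ph$image, cfg)
  b <- preprocess_volume(ph$image, cfg)
  expect_identical(a$data, b$data)
})
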