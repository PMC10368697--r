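test_that("phantom generation is deterministic given the spec seed", {
  sp <- phantom_spec(volume_shape = c(40, 40, 40), n_vessels = 2,
                     vessel_radius_range_mm = c(0.5, 1.2),
                     n_aneurysms = 1, aneurysm_diameter_range_mm = c(1.8, 5),
                     rician_sigma = 10, bias_amplitude = 0.2, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$vessel_mask$data, b$vessel_mask$data)
  expect_identical(a$aneurysm_mask$data, b$aneurysm_mask$data)
})

test_that("a phantom without aneurysms has vessels but an empty lesion mask", {
  ph <- quick_phantom(seed = 2, n_aneurysms = 0)
  expect_false(any(ph$aneurysm_mask$data))
  expect_true(any(ph$vessel_mask$data))
})

test_that("a straight noise-free tube matches the analytic cylinder volume", {
  sp <- phantom_spec(volume_shape = c(64, 40, 40), spacing_mm = rep(0.3, 3),
                     n_vessels = 1, vessel_radius_range_mm = c(1.5, 1.5),
                     n_aneurysms = 0, rician_sigma = 0, bias_amplitude = 0,
                     vessel_style = "straight", seed = 5)
  ph <- generate_phantom(sp)
  co <- which(ph$vessel_mask$data, arr.ind = TRUE)
  axis <- which.max(apply(co, 2, function(x) diff(range(x))))
  len_vox <- diff(range(co[, axis])) + 1
  analytic <- pi * (1.5 / 0.3)^2 * len_vox
  expect_lt(abs(sum(ph$vessel_mask$data) - analytic) / analytic, 0.05)
})

test_that("vessels are brighter than background when noise and bias are off", {
  ph <- quick_phantom(seed = 3, noise = 0, bias = 0)
  inside <- mean(ph$image$data[ph$vessel_mask$data])
  outside <- mean(ph$image$data[!ph$vessel_mask$data & !ph$aneurysm_mask$data])
  expect_gt(inside, outside)
})

test_that("every aneurysm component touches the vessel tree", {
  for (seed in 1:4) {
    ph <- quick_phantom(seed = seed, n_aneurysms = 2, shape = c(56, 56, 56))
    lab <- skelpatch:::label26_cpp(ph$aneurysm_mask$data,
                                   dim(ph$aneurysm_mask$data))
    for (k in seq_len(attr(lab, "n_components"))) {
      comp <- array(lab == k, dim(lab))
      grown <- skelpatch:::dilate_ball_cpp(comp, dim(comp), 1.8)
      expect_true(any(grown & ph$vessel_mask$data),
                  info = sprintf("seed %d component %d", seed, k))
    }
  }
})

test_that("aneurysm centers lie inside the aneurysm mask", {
  ph <- quick_phantom(seed = 9)
  for (a in ph$aneurysm_centers) {
    p <- a$center_vox
    nb <- ph$aneurysm_mask$data[
      max(1, p[1] - 1):min(dim(ph$aneurysm_mask$data)[1], p[1] + 1),
      max(1, p[2] - 1):min(dim(ph$aneurysm_mask$data)[2], p[2] + 1),
      max(1, p[3] - 1):min(dim(ph$aneurysm_mask$data)[3], p[3] + 1)]
    expect_true(any(nb))
  }
})

test_that("a spec whose smallest aneurysm cannot fit is rejected", {
  expect_error(
    phantom_spec(volume_shape = c(32, 32, 32), spacing_mm = rep(0.3, 3),
                 aneurysm_diameter_range_mm = c(30, 32.6)),
    "cannot fit")
})

test_that("size mixture respects the clinical range and strata proportions", {
  expect_identical(sample_size_mix(0), numeric(0))
  d1 <- sample_size_mix(1, seed = 3)
  expect_true(d1 >= 1.8 && d1 <= 32.6)
  # stratum counts within multinomial 99% bounds around (130, 21, 3)/154
  n <- 154
  d <- sample_size_mix(n, seed = 2)
  counts <- c(sum(d < 5), sum(d >= 5 & d <= 10), sum(d > 10))
  probs <- c(130, 21, 3) / 154
  for (k in 1:3) {
    lo <- qbinom(0.005, n, probs[k])
    hi <- qbinom(0.995, n, probs[k])
    expect_true(counts[k] >= lo && counts[k] <= hi,
                info = sprintf("stratum %d count %d outside [%d, %d]",
                               k, counts[k], lo, hi))
  }
  expect_identical(sample_size_mix(20, seed = 5), sample_size_mix(20, seed = 5))
})
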