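test_that("degenerate thresholds produce empty or full masks with a warning", {
  set.seed(1)
  img <- image_volume(array(runif(10^3), c(10, 10, 10)), rep(1, 3))
  expect_warning(
    m <- binarize_vessels(img, skeleton_config("fixed", threshold_value = 2)),
    "outside the data range")
  expect_false(any(m$data))
  expect_warning(
    f <- binarize_vessels(img, skeleton_config("fixed",
                                               threshold_value = min(img$data))),
    "outside the data range")
  expect_true(all(f$data))
})

test_that("midpoint thresholding of a noise-free phantom recovers the foreground exactly", {
  ph <- quick_phantom(seed = 2, noise = 0, bias = 0)
  thr <- (300 + 50) / 2
  m <- binarize_vessels(ph$image, skeleton_config("fixed", threshold_value = thr))
  expect_identical(m$data, ph$vessel_mask$data | ph$aneurysm_mask$data)
})

test_that("component filtering keeps only large components", {
  d <- c(40, 20, 20)
  m <- array(FALSE, d)
  m[2:3, 2:3, 2:3] <- TRUE            # 8 voxels
  m[10:30, 5:15, 5:15] <- TRUE        # 21*11*11 = 2541 voxels
  mask <- binary_mask(m, rep(1, 3))
  expect_identical(filter_components(mask, 0)$data, m)
  kept <- filter_components(mask, 2000)$data
  expect_identical(sum(kept), 2541L)
  expect_false(any(kept[2:3, 2:3, 2:3]))
})

test_that("filtered component sizes agree with a flood-fill oracle", {
  for (seed in 1:3) {
    m <- random_blob_mask(seed, c(20, 20, 20), n_balls = 5)
    mask <- binary_mask(m, rep(1, 3))
    min_v <- 60
    out <- filter_components(mask, min_v)$data
    sizes_in <- component_sizes_26(m)
    sizes_out <- component_sizes_26(out)
    expect_true(all(sizes_out >= min_v))
    expect_identical(sum(sizes_out), sum(sizes_in[sizes_in >= min_v]))
  }
})

test_that("region growing at zero tolerance is the identity on threshold masks", {
  ph <- quick_phantom(seed = 3, noise = 5)
  img <- ph$image
  thr <- quantile(img$data, 0.95)
  m <- binarize_vessels(img, skeleton_config("fixed", threshold_value = thr))
  grown <- region_grow(m, img, tolerance = 0)
  expect_identical(grown$data, m$data)
})

test_that("region growing bridges a one-voxel dim gap in a tube", {
  d <- c(30, 9, 9)
  img <- array(0, d)
  img[2:29, 4:6, 4:6] <- 100
  img[15, 4:6, 4:6] <- 95  # dim slice just below threshold
  iv <- image_volume(img, rep(1, 3))
  m <- binarize_vessels(iv, skeleton_config("fixed", threshold_value = 100))
  expect_identical(count_components_26(m$data), 2L)
  grown <- region_grow(m, iv, tolerance = 0.1)
  expect_identical(count_components_26(grown$data), 1L)
  expect_true(all(m$data[grown$data] | TRUE))  # superset check below
  expect_true(all(grown$data[m$data]))
})

test_that("region growing never exceeds the relaxed-threshold superset", {
  ph <- quick_phantom(seed = 4, noise = 10)
  img <- ph$image
  thr <- as.numeric(quantile(img$data, 0.97))
  m <- binarize_vessels(img, skeleton_config("fixed", threshold_value = thr))
  grown <- region_grow(m, img, tolerance = 0.1)
  superset <- img$data >= thr - 0.1 * abs(thr)
  expect_true(all(superset[grown$data]))
})

test_that("morphological closing fills interior holes and is idempotent", {
  d <- c(12, 12, 12)
  m <- array(FALSE, d)
  m[3:9, 3:9, 3:9] <- TRUE
  m[6, 6, 6] <- FALSE
  mask <- binary_mask(m, rep(1, 3))
  expect_identical(close_holes(mask, 0)$data, m)
  closed <- close_holes(mask, 1)
  expect_true(closed$data[6, 6, 6])
  expect_identical(close_holes(closed, 1)$data, closed$data)
})

test_that("thinning leaves a one-voxel line unchanged and an empty mask empty", {
  d <- c(30, 9, 9)
  line <- array(FALSE, d)
  line[3:27, 5, 5] <- TRUE
  sk <- thin_to_skeleton(binary_mask(line, rep(1, 3)))
  expect_identical(skeleton_mask(sk), line)
  empty <- thin_to_skeleton(binary_mask(array(FALSE, d), rep(1, 3)))
  expect_identical(nrow(empty$coords), 0L)
})

test_that("a solid rod thins to a single curve of about its length", {
  d <- c(50, 9, 9)
  rod <- array(FALSE, d)
  rod[1:50, 2:6, 2:6] <- TRUE
  sk <- thin_to_skeleton(binary_mask(rod, rep(1, 3)))
  m <- skeleton_mask(sk)
  expect_identical(count_components_26(m), 1L)
  expect_true(abs(nrow(sk$coords) - 50) <= 10)  # within 20% of the length
  # a curve: no voxel has more than two 26-neighbors
  co <- sk$coords
  dd <- as.matrix(dist(co))
  expect_lte(max(colSums(dd > 0 & dd < 1.8)), 2)
})

test_that("thinning preserves topology, subset and idempotence on fuzzed masks", {
  for (seed in 1:12) {
    m <- random_blob_mask(seed, c(20, 20, 20), n_balls = 3,
                          with_tube = seed %% 2 == 0)
    mask <- binary_mask(m, rep(1, 3))
    sk <- skeleton_mask(thin_to_skeleton(mask))
    expect_true(all(m[sk]), info = paste("subset, seed", seed))
    expect_identical(count_components_26(sk), count_components_26(m),
                     info = paste("topology, seed", seed))
    sk2 <- skeleton_mask(thin_to_skeleton(binary_mask(sk, rep(1, 3))))
    expect_identical(sk2, sk, info = paste("idempotence, seed", seed))
    expect_false(has_thick_block(sk), info = paste("thinness, seed", seed))
  }
})

test_that("phantom skeletons track the ground-truth centerlines", {
  ph <- quick_phantom(seed = 6, noise = 0, bias = 0, shape = c(56, 56, 56),
                      n_aneurysms = 0)
  thr <- (300 + 50) / 2
  sk <- vessel_skeleton(ph$image,
                        skeleton_config("fixed", threshold_value = thr,
                                        min_component_voxels = 100,
                                        closing_radius_vox = 1))
  pts <- do.call(rbind, ph$centerlines) / 0.3  # mm -> voxel units
  co <- sk$skeleton$coords - 1
  dists <- skelpatch:::min_dist_mm_cpp(co, pts, c(1, 1, 1))
  max_r_vox <- max(ph$vessel_radii_mm) / 0.3
  expect_gte(mean(dists <= max_r_vox + 1), 0.95)
})
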