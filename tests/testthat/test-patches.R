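make_case_with_mask <- function(mask, img_vals = NULL, spacing = rep(0.3, 3)) {
  d <- dim(mask)
  img <- image_volume(img_vals %||% array(rnorm(prod(d)), d), spacing)
  list(image = img, aneurysm_mask = binary_mask(mask, spacing))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("positive patches always contain the whole lesion", {
  d <- c(40, 40, 40)
  m <- array(FALSE, d)
  m[20, 20, 20] <- m[21, 20, 20] <- m[20, 21, 20] <- TRUE  # 3-voxel lesion
  cs <- make_case_with_mask(m)
  plan <- sampling_plan(patch_size = c(16, 16, 16),
                        n_positive_per_aneurysm = 5, seed = 3)
  ps <- sample_positive_patches(cs$image, cs$aneurysm_mask, plan)
  expect_length(ps, 5)
  for (p in ps) {
    expect_identical(p$label, 1L)
    expect_identical(sum(p$mask_patch), 3L)
  }
})

test_that("a lesion filling the patch forces a unique origin", {
  d <- c(20, 20, 20)
  m <- array(FALSE, d)
  m[5:12, 5:12, 5:12] <- TRUE  # bounding box exactly 8^3
  cs <- make_case_with_mask(m)
  plan <- sampling_plan(patch_size = c(8, 8, 8),
                        n_positive_per_aneurysm = 4, seed = 1)
  ps <- sample_positive_patches(cs$image, cs$aneurysm_mask, plan)
  origins <- unique(t(vapply(ps, function(p) p$origin_vox, integer(3))))
  expect_identical(nrow(origins), 1L)
  expect_identical(as.integer(origins[1, ]), c(5L, 5L, 5L))
})

test_that("oversized lesions are rejected with a descriptive error", {
  d <- c(30, 30, 30)
  m <- array(FALSE, d)
  m[2:20, 5, 5] <- TRUE
  cs <- make_case_with_mask(m)
  plan <- sampling_plan(patch_size = c(8, 8, 8))
  expect_error(sample_positive_patches(cs$image, cs$aneurysm_mask, plan),
               "exceeds patch size")
})

test_that("sampled origins fall exactly in the brute-force admissible set", {
  for (seed in 1:3) {
    ph <- quick_phantom(seed = seed, shape = c(40, 40, 40), diam = c(1.8, 4))
    plan <- sampling_plan(patch_size = c(16, 16, 16),
                          n_positive_per_aneurysm = 25, seed = seed)
    ps <- sample_positive_patches(ph$image, ph$aneurysm_mask, plan)
    co <- which(ph$aneurysm_mask$data, arr.ind = TRUE)
    admissible <- brute_force_origins(co, c(16, 16, 16), dim(ph$aneurysm_mask$data))
    keys <- apply(admissible, 1, paste, collapse = ",")
    drawn <- vapply(ps, function(p) paste(p$origin_vox, collapse = ","), "")
    expect_true(all(drawn %in% keys), info = paste("seed", seed))
    # the brute-force set is exactly the box the sampler draws from
    lo <- apply(co, 2, min)
    hi <- apply(co, 2, max)
    expect_identical(nrow(admissible), as.integer(prod(lo - (hi - 16L))))
  }
})

test_that("negative patches are aneurysm-free and respect the exclusion radius", {
  pc <- tiny_prepared_case(seed = 2)
  plan <- sampling_plan(patch_size = c(16, 16, 16),
                        min_negative_distance_mm = 3, seed = 4)
  neg <- sample_negative_patches(pc$image, pc$skeleton, pc$aneurysm_mask,
                                 plan, n_needed = 12)
  expect_gt(length(neg), 0)
  an <- which(pc$aneurysm_mask$data, arr.ind = TRUE)
  amask <- array(as.integer(pc$aneurysm_mask$data), dim(pc$aneurysm_mask$data))
  for (p in neg) {
    expect_identical(p$label, 0L)
    expect_identical(sum(p$mask_patch), 0L)
    # independent crop-and-check oracle
    oracle_crop <- crop_patch(amask, p$origin_vox, c(16L, 16L, 16L), 0L)
    expect_identical(sum(oracle_crop), 0L)
  }
})

test_that("negatives on an aneurysm-free phantom all carry label zero", {
  ph <- quick_phantom(seed = 5, n_aneurysms = 0)
  img <- preprocess_volume(ph$image, preprocess_config())
  sk <- vessel_skeleton(img, skeleton_config("auto", min_component_voxels = 200))
  plan <- sampling_plan(patch_size = c(16, 16, 16), seed = 1)
  neg <- sample_negative_patches(img, sk$skeleton,
                                 binary_mask(array(FALSE, dim(img$data)),
                                             img$spacing),
                                 plan, n_needed = 10)
  expect_length(neg, 10)
  expect_true(all(vapply(neg, function(p) p$label, 0L) == 0L))
  expect_identical(sample_negative_patches(img, sk$skeleton,
                                           ph$aneurysm_mask, plan, 0),
                   list())
})

test_that("build_dataset enforces the exact ratio for every k in 1..5", {
  pc <- tiny_prepared_case(seed = 3)
  for (k in 1:5) {
    plan <- sampling_plan(patch_size = c(16, 16, 16), ratio = k,
                          n_positive_per_aneurysm = 3, seed = k)
    ds <- build_dataset(list(pc), plan)
    n_pos <- sum(ds$manifest$label == 1)
    n_neg <- sum(ds$manifest$label == 0)
    expect_identical(n_neg, k * n_pos)
  }
})

test_that("dataset construction is reproducible under a fixed seed", {
  pc1 <- tiny_prepared_case(seed = 4, case_id = "a")
  pc2 <- tiny_prepared_case(seed = 5, case_id = "b")
  plan <- sampling_plan(patch_size = c(16, 16, 16), ratio = 2,
                        n_positive_per_aneurysm = 3, seed = 9)
  d1 <- build_dataset(list(pc1, pc2), plan)
  d2 <- build_dataset(list(pc1, pc2), plan)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(lapply(d1$samples, function(s) s$image_patch),
                   lapply(d2$samples, function(s) s$image_patch))
})

test_that("shuffling the case order leaves the sampled multiset unchanged", {
  pc1 <- tiny_prepared_case(seed = 7, case_id = "a")
  pc2 <- tiny_prepared_case(seed = 8, case_id = "b")
  plan <- sampling_plan(patch_size = c(16, 16, 16), ratio = 2,
                        n_positive_per_aneurysm = 3, seed = 9)
  d1 <- build_dataset(list(pc1, pc2), plan)
  d2 <- build_dataset(list(pc2, pc1), plan)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(d1$manifest), key(d2$manifest))
})

test_that("an all-negative cohort is rejected for training", {
  ph <- quick_phantom(seed = 6, n_aneurysms = 0)
  img <- preprocess_volume(ph$image, preprocess_config())
  sk <- vessel_skeleton(img, skeleton_config("auto", min_component_voxels = 200))
  case <- list(case_id = "neg", image = img,
               aneurysm_mask = binary_mask(array(FALSE, dim(img$data)),
                                           img$spacing),
               skeleton = sk$skeleton)
  expect_error(build_dataset(list(case), sampling_plan(patch_size = c(16, 16, 16))),
               "no positive patches")
})
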