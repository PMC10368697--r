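# A micro patch set: a bright cube lesion in half the patches.
micro_patch_set <- function(n_pos = 4, n_neg = 4, d = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  samples <- list()
  for (i in seq_len(n_pos)) {
    img <- array(rnorm(prod(d), 0, 0.3), d)
    msk <- array(0L, d)
    msk[3:6, 3:6, 3:6] <- 1L
    img[msk == 1] <- img[msk == 1] + 3
    samples[[length(samples) + 1]] <-
      skelpatch:::new_patch_sample(img, msk, c(1L, 1L, 1L), paste0("p", i))
  }
  for (i in seq_len(n_neg)) {
    img <- array(rnorm(prod(d), 0, 0.3), d)
    samples[[length(samples) + 1]] <-
      skelpatch:::new_patch_sample(img, array(0L, d), c(1L, 1L, 1L),
                                   paste0("n", i))
  }
  manifest <- data.frame(
    case_id = vapply(samples, function(s) s$case_id, ""),
    origin_x = 1L, origin_y = 1L, origin_z = 1L,
    label = vapply(samples, function(s) s$label, 0L))
  structure(list(samples = samples, manifest = manifest,
                 plan = sampling_plan(patch_size = d)),
            class = "patch_set")
}

test_that("training reduces the loss on a micro problem and is seeded", {
  ps <- micro_patch_set()
  cfg <- train_config(batch_size = 4, epochs = 5, lr = 5e-3, seed = 1)
  m1 <- build_model(tiny_net(), seed = 5)
  fit1 <- train_network(m1, ps, NULL, cfg, loss_config())
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  m2 <- build_model(tiny_net(), seed = 5)
  fit2 <- train_network(m2, ps, NULL, cfg, loss_config())
  expect_identical(fit1$history$train_loss[1], fit2$history$train_loss[1])
})

test_that("disabling the auxiliary head zeroes the aux term exactly", {
  ps <- micro_patch_set()
  m <- build_model(tiny_net(aux = character(0)), seed = 2)
  batch <- skelpatch:::stack_batch(ps$samples[1:4])
  ctx <- skelpatch:::ag_ctx()
  bl <- skelpatch:::batch_loss(m, ctx, batch, loss_config(), training = TRUE)
  expect_identical(bl$aux, 0)
  m2 <- build_model(tiny_net(), seed = 2)
  ctx2 <- skelpatch:::ag_ctx()
  bl2 <- skelpatch:::batch_loss(m2, ctx2, batch,
                                loss_config(aux_weight = 0), training = TRUE)
  expect_identical(bl2$aux, 0)
})

test_that("a constant-positive model predicts exactly the tiled footprint", {
  m <- build_model(tiny_net(aux = character(0)), seed = 3)
  # force the final projection to a large positive constant
  m$net$fin$w$val[] <- 0
  m$net$fin$b$val <- 20
  pc <- tiny_prepared_case(seed = 7, shape = c(40, 40, 40))
  pv <- predict_volume(m, pc$image, pc$skeleton, patch_size = c(16, 16, 16))
  covered <- array(FALSE, dim(pc$image$data))
  for (i in seq_len(nrow(pv$patch_origins))) {
    o <- pv$patch_origins[i, ]
    hi <- pmin(o + 15L, dim(covered))
    covered[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3]] <- TRUE
  }
  expect_identical(pv$mask$data, covered)
  # no-overlap stride: probabilities inside the footprint stay saturated
  expect_true(all(pv$seg_probability$data[covered] > 0.999))
  expect_true(all(pv$seg_probability$data[!covered] == 0))
})

test_that("overlap averaging equals an accumulate-and-count oracle", {
  m <- build_model(tiny_net(aux = character(0)), seed = 4)
  pc <- tiny_prepared_case(seed = 8, shape = c(40, 40, 40))
  ps <- c(16L, 16L, 16L)
  pv <- predict_volume(m, pc$image, pc$skeleton, patch_size = ps,
                       stride = c(8L, 8L, 8L))
  acc <- array(0, dim(pc$image$data))
  cnt <- array(0, dim(pc$image$data))
  for (i in seq_len(nrow(pv$patch_origins))) {
    o <- pv$patch_origins[i, ]
    xb <- crop_patch(pc$image$data, o, ps, 0)
    pr <- predict_patches(m, array(xb, c(ps, 1)))
    acc <- skelpatch:::paste_patch(acc, pr$seg_probability[, , , 1], o)
    cnt <- skelpatch:::paste_patch(cnt, array(1, ps), o)
  }
  expected <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  expect_equal(pv$seg_probability$data, expected, tolerance = 1e-12)
})

test_that("an empty skeleton yields an all-zero prediction with a warning", {
  m <- build_model(tiny_net(aux = character(0)), seed = 5)
  pc <- tiny_prepared_case(seed = 9, shape = c(40, 40, 40))
  empty <- skeleton_voxels(matrix(integer(0), 0, 3), dim(pc$image$data),
                           pc$image$spacing)
  expect_warning(pv <- predict_volume(m, pc$image, empty,
                                      patch_size = c(16, 16, 16)),
                 "empty skeleton")
  expect_false(any(pv$mask$data))
  expect_true(all(pv$seg_probability$data == 0))
})
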