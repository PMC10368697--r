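test_that("the classic configuration reports 23 convolutional layers", {
  m <- build_model(network_spec(depth = 4, base_channels = 2,
                                block_style = "plain", attention = FALSE,
                                aux_tap_levels = character(0)), seed = 1)
  expect_identical(m$n_conv_layers, 23L)
})

test_that("forward pass preserves patch shape and bounds aux probabilities", {
  m <- build_model(network_spec(depth = 2, base_channels = 4,
                                block_style = "residual", attention = TRUE,
                                aux_tap_levels = c("bridge", "mid")), seed = 2)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  pr <- predict_patches(m, x)
  expect_identical(dim(pr$seg_probability), c(16L, 16L, 16L, 2L))
  expect_true(all(pr$seg_probability >= 0 & pr$seg_probability <= 1))
  expect_length(pr$aux_probability, 2)
  expect_true(all(pr$aux_probability >= 0 & pr$aux_probability <= 1))
})

test_that("inputs not divisible by 2^depth are rejected with a padding hint", {
  m <- build_model(network_spec(depth = 3, base_channels = 2,
                                aux_tap_levels = character(0)), seed = 1)
  x <- array(rnorm(12^3), c(12, 12, 12))
  expect_error(predict_patches(m, x), "divisible")
})

test_that("model initialization is deterministic given the seed", {
  sp <- network_spec(depth = 2, base_channels = 4, block_style = "residual",
                     attention = TRUE)
  a <- build_model(sp, seed = 7)
  b <- build_model(sp, seed = 7)
  c_ <- build_model(sp, seed = 8)
  pa <- lapply(a$params, function(p) p$val)
  expect_identical(pa, lapply(b$params, function(p) p$val))
  expect_false(identical(pa, lapply(c_$params, function(p) p$val)))
})

test_that("model checkpoints round-trip through save and load", {
  m <- build_model(tiny_net(), seed = 11)
  x <- array(rnorm(8^3), c(8, 8, 8))
  before <- predict_patches(m, x)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  after <- predict_patches(m2, x)
  expect_identical(after$seg_probability, before$seg_probability)
  expect_identical(after$aux_probability, before$aux_probability)
})

test_that("gradients flow to the encoder through both the segmentation and aux paths", {
  m <- build_model(network_spec(depth = 1, base_channels = 2,
                                block_style = "plain",
                                aux_tap_levels = "bridge"), seed = 3)
  set.seed(4)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 1, 2))
  g <- array(0, c(8, 8, 8, 1, 2)); g[3:5, 3:5, 3:5, 1, ] <- 1
  first_conv <- m$net$enc[[1]]$u1$conv$w
  grad_norm_for <- function(loss_builder) {
    ctx <- skelpatch:::ag_ctx()
    out <- skelpatch:::forward_unet(m, ctx, x, training = TRUE)
    loss <- loss_builder(ctx, out)
    skelpatch:::ag_zero_grads(m$params)
    skelpatch:::ag_backward(ctx, loss)
    sqrt(sum(first_conv$grad^2))
  }
  seg_norm <- grad_norm_for(function(ctx, out) {
    p <- skelpatch:::op_sigmoid(ctx, out$seg)
    skelpatch:::op_dice_loss(ctx, p, g)
  })
  aux_norm <- grad_norm_for(function(ctx, out)
    skelpatch:::op_bce_logits(ctx, out$aux$bridge, c(1, 1)))
  expect_true(is.finite(seg_norm) && seg_norm > 0)
  expect_true(is.finite(aux_norm) && aux_norm > 0)
})
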