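test_that("the loss is minimal at a perfect prediction", {
  d <- c(6, 6, 6)
  g <- array(0, d); g[2:4, 2:4, 2:4] <- 1
  pred <- list(seg_probability = g, aux_probability = 1)
  l <- compute_loss(pred, g, 1L, loss_config())
  expect_lt(l$terms[["dice"]], 0.02)           # within smoothing epsilon
  expect_lt(l$terms[["tversky_focal"]], 0.02)
  expect_lt(l$terms[["aux"]], 1e-6)
  worse <- compute_loss(list(seg_probability = array(0.5, d),
                             aux_probability = 0.5), g, 1L, loss_config())
  expect_lt(l$total, worse$total)
})

test_that("Tversky with alpha = beta = 0.5 and gamma = 1 equals soft Dice", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4^3)
    g <- rbinom(4^3, 1, 0.3)
    expect_lt(abs(tversky_focal_value(p, g, 0.5, 0.5, 1) -
                  dice_loss_value(p, g)), 1e-6)
  }
})

test_that("loss terms match a direct-summation oracle on 4^3 tensors", {
  set.seed(2)
  for (i in 1:10) {
    d <- c(4, 4, 4)
    p <- array(runif(prod(d)), d)
    g <- array(rbinom(prod(d), 1, 0.4), d)
    if (!any(g > 0)) g[1, 1, 1] <- 1
    cfg <- loss_config()
    l <- compute_loss(list(seg_probability = p, aux_probability = 0.7),
                      g, 1L, cfg)
    expect_lt(abs(l$terms[["dice"]] - dice_oracle(p, g)), 1e-6)
    expect_lt(abs(l$terms[["tversky_focal"]] -
                  tversky_oracle(p, g, cfg$tversky_alpha, cfg$tversky_beta,
                                 cfg$focal_gamma)), 1e-6)
    expect_lt(abs(l$terms[["cross_entropy"]] - bce_oracle(p, g)), 1e-6)
    expect_lt(abs(l$terms[["aux"]] - bce_oracle(0.7, 1)), 1e-6)
    # total is the mean of segmentation and classifier losses
    seg <- sum(l$terms[c("dice", "tversky_focal", "cross_entropy")])
    expect_lt(abs(l$total - mean(c(seg, l$terms[["aux"]]))), 1e-9)
  }
})

test_that("an inconsistent label/mask pair is rejected", {
  d <- c(4, 4, 4)
  g <- array(0, d); g[1, 1, 1] <- 1
  pred <- list(seg_probability = array(0.2, d))
  expect_error(compute_loss(pred, g, 0L), "label is 0")
  expect_error(compute_loss(pred, array(0, d), 1L), "label is 1")
})

test_that("the loss is non-negative and handles all-empty targets", {
  d <- c(4, 4, 4)
  pred <- list(seg_probability = array(0, d), aux_probability = 0)
  l <- compute_loss(pred, array(0, d), 0L, loss_config())
  expect_gte(l$total, 0)
  expect_true(is.finite(l$total))  # smoothed dice: no division by zero
})

test_that("differentiable loss nodes agree with the value-level functions", {
  set.seed(3)
  d <- c(4, 4, 4, 1, 2)
  pv <- array(runif(prod(d)), d)
  g <- array(rbinom(prod(d), 1, 0.3), d)
  ctx <- skelpatch:::ag_ctx()
  p <- skelpatch:::ag_node(ctx, pv)
  dn <- skelpatch:::op_dice_loss(ctx, p, g)
  per_sample <- c(dice_loss_value(pv[, , , , 1], g[, , , , 1]),
                  dice_loss_value(pv[, , , , 2], g[, , , , 2]))
  expect_lt(abs(dn$val - mean(per_sample)), 1e-9)
  tn <- skelpatch:::op_tversky_focal(ctx, p, g, 0.3, 0.7, 4 / 3)
  per_sample_t <- c(tversky_focal_value(pv[, , , , 1], g[, , , , 1], 0.3, 0.7, 4 / 3),
                    tversky_focal_value(pv[, , , , 2], g[, , , , 2], 0.3, 0.7, 4 / 3))
  expect_lt(abs(tn$val - mean(per_sample_t)), 1e-9)
})
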