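test_that("confusion counts handle the degenerate corners", {
  all_right <- confusion_from_patches(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0))
  expect_identical(all_right$FP, 0L)
  expect_identical(all_right$FN, 0L)
  inverted <- confusion_from_patches(rep(1, 5), rep(0, 5))
  expect_identical(inverted$TP, 0L)
  expect_identical(inverted$TN, 0L)
  expect_identical(inverted$FN, 0L)
  expect_identical(inverted$FP, 5L)
  expect_error(confusion_from_patches(numeric(0), numeric(0)), "no predictions")
})

test_that("confusion counts agree with a loop-and-count oracle", {
  set.seed(1)
  prob <- runif(200)
  lab <- rbinom(200, 1, 0.3)
  cc <- confusion_from_patches(prob, lab)
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:200) {
    pred <- prob[i] > 0.5
    if (pred && lab[i] == 1) tp <- tp + 1L
    if (pred && lab[i] == 0) fp <- fp + 1L
    if (!pred && lab[i] == 0) tn <- tn + 1L
    if (!pred && lab[i] == 1) fn <- fn + 1L
  }
  expect_identical(unlist(unclass(cc)), c(TP = tp, FP = fp, TN = tn, FN = fn))
})

test_that("the metric panel matches a direct-formula oracle on fuzzed counts", {
  set.seed(2)
  for (i in 1:100) {
    counts <- as.list(rpois(4, 20))
    names(counts) <- c("TP", "FP", "TN", "FN")
    panel <- metric_panel(counts)
    oracle <- panel_oracle(counts$TP, counts$FP, counts$TN, counts$FN)
    for (m in names(oracle)) {
      if (is.na(oracle[[m]])) expect_true(is.na(panel[[m]]))
      else expect_lt(abs(panel[[m]] - oracle[[m]]), 1e-12)
    }
  }
})

test_that("simple panels evaluate exactly and percent scaling works", {
  perfect <- metric_panel(list(TP = 1, FN = 0, FP = 0, TN = 1))
  expect_true(all(perfect == 1))
  expect_identical(metric_panel(list(TP = 3, FP = 1, TN = 0, FN = 0))[["ppv"]],
                   0.75)
  expect_identical(
    metric_panel(list(TP = 3, FP = 1, TN = 0, FN = 0), percent = TRUE)[["ppv"]],
    75)
})

test_that("zero denominators give NA, never zero", {
  p <- metric_panel(list(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(is.na(p[["ppv"]]))
  expect_true(is.na(p[["sensitivity"]]))
  expect_identical(p[["specificity"]], 1)
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(3)
  for (i in 1:20) {
    tp <- rpois(1, 10) + 1; fn <- rpois(1, 5) + 1
    tn <- rpois(1, 10) + 1; fp <- rpois(1, 5) + 1
    p <- metric_panel(list(TP = tp, FP = fp, TN = tn, FN = fn))
    npos <- tp + fn; nneg <- tn + fp
    weighted <- (npos * p[["sensitivity"]] + nneg * p[["specificity"]]) /
      (npos + nneg)
    expect_lt(abs(p[["accuracy"]] - weighted), 1e-12)
  }
})

test_that("DSC evaluates its worked cases exactly", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[2:3, 2:3, 2:3] <- TRUE
  expect_identical(dsc(a, a), 1)
  b <- array(FALSE, d); b[7:8, 7:8, 7:8] <- TRUE
  expect_identical(dsc(a, b), 0)
  # 8-voxel cube against a copy shifted to overlap exactly 4 voxels
  gt <- array(FALSE, d); gt[4:5, 4:5, 4:5] <- TRUE
  pr <- array(FALSE, d); pr[4:5, 4:5, 5:6] <- TRUE
  expect_identical(dsc(gt, pr), 0.5)
})

test_that("DSC is symmetric, bounded and errors on grid mismatch", {
  set.seed(4)
  for (i in 1:10) {
    a <- random_blob_mask(i, c(14, 14, 14))
    b <- random_blob_mask(i + 100, c(14, 14, 14))
    expect_identical(dsc(a, b), dsc(b, a))
    expect_gte(dsc(a, b), 0)
    expect_lte(dsc(a, b), 1)
  }
  expect_error(dsc(array(FALSE, c(4, 4, 4)), array(FALSE, c(5, 5, 5))),
               "do not match")
  expect_true(is.na(dsc(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4)))))
})

test_that("seg_scores summarizes per-case DSC over defined cases", {
  d <- c(8, 8, 8)
  m1 <- array(FALSE, d); m1[2:4, 2:4, 2:4] <- TRUE
  sc <- seg_scores(list(m1, m1), list(m1, array(FALSE, d)))
  expect_identical(sc$dsc, c(1, 0))
  expect_identical(attr(sc, "mean_dsc"), 0.5)
})

test_that("size strata bin the clinical boundaries as documented", {
  s <- size_stratum(c(2, 5, 7, 10, 15))
  expect_identical(as.character(s),
                   c("<5 mm", "5-10 mm", "5-10 mm", "5-10 mm", ">10 mm"))
})

test_that("the stratified report matches a group-by oracle and keeps empty strata NA", {
  cm <- data.frame(dsc = c(0.8, 0.6, 0.4, 0.2), accuracy = c(1, 0.9, 0.8, 0.7))
  di <- c(2, 3, 7, 15)
  rep_ <- stratified_report(cm, di)
  expect_identical(rep_$n, c(2L, 1L, 1L))
  expect_equal(rep_$mean_dsc, c(mean(c(0.8, 0.6)), 0.4, 0.2))
  expect_equal(rep_$mean_accuracy, c(0.95, 0.8, 0.7))
  only_small <- stratified_report(data.frame(dsc = c(0.5, 0.7)), c(2, 3))
  expect_identical(only_small$n, c(2L, 0L, 0L))
  expect_true(all(is.na(only_small$mean_dsc[2:3])))
  expect_warning(stratified_report(data.frame(dsc = c(0.5, 0.7)), c(2, NA)),
                 "without diameter")
})
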