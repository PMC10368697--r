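#' Loss configuration for the multi-task network
#'
#' The segmentation loss is a weighted sum of soft Dice, Tversky-focal and
#' voxel-wise cross-entropy terms; auxiliary classifier heads contribute a
#' binary cross-entropy term, and the total is the average of the
#' segmentation and classifier losses. With `tversky_alpha = tversky_beta =
#' 0.5` and `focal_gamma = 1` the Tversky-focal term reduces exactly to the
#' soft Dice loss. Defaults weight false negatives more than false
#' positives (alpha 0.3, beta 0.7, gamma 4/3), the usual choice for small
#' lesions.
#'
#' @param dice,tversky_focal,cross_entropy non-negative weights of the
#'   segmentation terms; at least one must be positive.
#' @param tversky_alpha,tversky_beta false-positive / false-negative weights
#'   of the Tversky index, in `[0, 1]`.
#' @param focal_gamma focusing exponent (>= 0) applied to `1 - TI`.
#' @param aux_weight weight of the auxiliary binary cross-entropy (0
#'   disables the auxiliary term).
#' @param smooth additive smoothing constant of the Dice/Tversky terms,
#'   which keeps the loss defined for all-empty targets.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(dice = 1, tversky_focal = 1, cross_entropy = 1,
                        tversky_alpha = 0.3, tversky_beta = 0.7,
                        focal_gamma = 4 / 3, aux_weight = 1, smooth = 1) {
  stopifnot(dice >= 0, tversky_focal >= 0, cross_entropy >= 0,
            dice + tversky_focal + cross_entropy > 0,
            tversky_alpha >= 0, tversky_alpha <= 1,
            tversky_beta >= 0, tversky_beta <= 1,
            focal_gamma >= 0, aux_weight >= 0, smooth > 0)
  structure(list(dice = dice, tversky_focal = tversky_focal,
                 cross_entropy = cross_entropy,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 focal_gamma = focal_gamma, aux_weight = aux_weight,
                 smooth = smooth),
            class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * g) + s) / (sum(p) + sum(g) + s)`, averaged over the
#' samples of a batch when `p` has a batch dimension.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param g binary target of the same shape.
#' @param smooth smoothing constant.
#' @return scalar loss in `[0, 1)`.
#' @export
dice_loss_value <- function(p, g, smooth = 1) {
  p <- as.vector(p); g <- as.vector(g)
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

#' Tversky focal loss
#'
#' `(1 - TI)^gamma` with
#' `TI = (TP + s) / (TP + alpha * FP + beta * FN + s)` on soft counts
#' `TP = sum(p g)`, `FP = sum(p (1-g))`, `FN = sum((1-p) g)`. Reduces to
#' [dice_loss_value()] when `alpha = beta = 0.5`, `gamma = 1`.
#'
#' @inheritParams dice_loss_value
#' @param alpha,beta false-positive / false-negative weights.
#' @param gamma focusing exponent.
#' @return scalar loss.
#' @export
tversky_focal_value <- function(p, g, alpha = 0.3, beta = 0.7, gamma = 4 / 3,
                                smooth = 1) {
  p <- as.vector(p); g <- as.vector(g)
  tp <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  s2 <- smooth / 2  # half the Dice smoothing: makes the alpha = beta = 0.5
                    # reduction to soft Dice exact for any smoothing
  ti <- (tp + s2) / (tp + alpha * fp + beta * fn + s2)
  (1 - ti)^gamma
}

#' Binary cross-entropy on probabilities
#'
#' @inheritParams dice_loss_value
#' @param eps probability clamp to keep the logarithm finite.
#' @return scalar mean cross-entropy.
#' @export
bce_value <- function(p, g, eps = 1e-7) {
  p <- pmin(pmax(as.vector(p), eps), 1 - eps)
  g <- as.vector(g)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Compute the multi-task loss with a per-term breakdown
#'
#' The segmentation loss is the weighted sum of the enabled terms on the
#' predicted probability map; the auxiliary loss is binary cross-entropy of
#' the patch-level probability against the patch label; the total is the
#' mean of the two (or the segmentation loss alone when the auxiliary term
#' is disabled or absent).
#'
#' @param pred a list with `seg_probability` (array in `[0, 1]`) and
#'   optionally `aux_probability` (scalar or vector in `[0, 1]`).
#' @param target_mask binary array (or [binary_mask()]) matching
#'   `seg_probability`.
#' @param target_label patch label in `{0, 1}`; must be 1 exactly when the
#'   target mask is nonempty.
#' @param cfg a [loss_config()].
#' @return list with `total` and `terms` (named numeric vector with dice,
#'   tversky_focal, cross_entropy, aux).
#' @export
compute_loss <- function(pred, target_mask, target_label,
                         cfg = loss_config()) {
  g <- if (inherits(target_mask, "binary_mask")) target_mask$data else target_mask
  g <- as.numeric(g)
  p <- pred$seg_probability
  if (inherits(p, "image_volume")) p <- p$data
  if (length(p) != length(g))
    stop("prediction and target shapes do not match")
  if (target_label == 0 && any(g > 0))
    stop("label is 0 but the target mask is nonempty")
  if (target_label == 1 && !any(g > 0))
    stop("label is 1 but the target mask is empty")
  terms <- c(
    dice = dice_loss_value(p, g, cfg$smooth),
    tversky_focal = tversky_focal_value(p, g, cfg$tversky_alpha,
                                        cfg$tversky_beta, cfg$focal_gamma,
                                        cfg$smooth),
    cross_entropy = bce_value(p, g),
    aux = 0)
  seg <- cfg$dice * terms["dice"] +
    cfg$tversky_focal * terms["tversky_focal"] +
    cfg$cross_entropy * terms["cross_entropy"]
  has_aux <- cfg$aux_weight > 0 && !is.null(pred$aux_probability)
  if (has_aux) {
    terms["aux"] <- bce_value(mean(pred$aux_probability), target_label)
    total <- mean(c(seg, cfg$aux_weight * terms["aux"]))
  } else {
    total <- as.numeric(seg)
  }
  list(total = as.numeric(total), terms = terms)
}

# ---- differentiable loss nodes (training path) ---------------------------

# Soft Dice loss per batch sample, averaged; p is a [X,Y,Z,1,N] node, g a
# numeric array of the same shape.
op_dice_loss <- function(ctx, p, g, smooth = 1) {
  d <- dim(p$val)
  sp <- prod(d[1:3]); N <- d[5]
  pm <- matrix(p$val, sp, N)
  gm <- matrix(g, sp, N)
  inter <- colSums(pm * gm)
  ps <- colSums(pm)
  gs <- colSums(gm)
  den <- ps + gs + smooth
  dice <- (2 * inter + smooth) / den
  ag_node(ctx, mean(1 - dice), bw = function(gr) {
    gp <- matrix(0, sp, N)
    for (n in seq_len(N))
      gp[, n] <- -(2 * gm[, n] * den[n] - (2 * inter[n] + smooth)) / den[n]^2
    ag_accum(p, array(gr * gp / N, d))
  })
}

op_tversky_focal <- function(ctx, p, g, alpha = 0.3, beta = 0.7,
                             gamma = 4 / 3, smooth = 1) {
  d <- dim(p$val)
  sp <- prod(d[1:3]); N <- d[5]
  pm <- matrix(p$val, sp, N)
  gm <- matrix(g, sp, N)
  tp <- colSums(pm * gm)
  fp <- colSums(pm * (1 - gm))
  fn <- colSums((1 - pm) * gm)
  s2 <- smooth / 2  # see tversky_focal_value: exact Dice reduction
  num <- tp + s2
  den <- tp + alpha * fp + beta * fn + s2
  ti <- num / den
  ag_node(ctx, mean((1 - ti)^gamma), bw = function(gr) {
    gp <- matrix(0, sp, N)
    for (n in seq_len(N)) {
      outer_g <- if (gamma == 1) 1 else gamma * (1 - ti[n])^(gamma - 1)
      dden <- gm[, n] + alpha * (1 - gm[, n]) - beta * gm[, n]
      dti <- (gm[, n] * den[n] - num[n] * dden) / den[n]^2
      gp[, n] <- -outer_g * dti
    }
    ag_accum(p, array(gr * gp / N, d))
  })
}

# Numerically stable binary cross-entropy on logits (mean over elements).
op_bce_logits <- function(ctx, z, t) {
  zv <- as.vector(z$val)
  tv <- as.vector(t)
  n <- length(zv)
  val <- mean(pmax(zv, 0) - zv * tv + log1p(exp(-abs(zv))))
  ag_node(ctx, val, bw = function(gr) {
    sg <- 1 / (1 + exp(-zv))
    ag_accum(z, array(gr * (sg - tv) / n, dim(z$val) %||% n))
  })
}

# Weighted sum of scalar nodes.
op_scalar_comb <- function(ctx, nodes, weights) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + weights[i] * nodes[[i]]$val
  ag_node(ctx, val, bw = function(gr) {
    for (i in seq_along(nodes)) ag_accum(nodes[[i]], gr * weights[i])
  })
}
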