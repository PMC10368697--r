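#' Training configuration
#'
#' Adaptive-moment (Adam) optimization with the reference hyperparameters:
#' batch size 16, learning rate 0.001, 500 epochs. Desk-scale experiments
#' override batch size and epoch count; see the package vignette for the
#' profiles used in the shipped experiments.
#'
#' @param batch_size patches per gradient step (>= 1).
#' @param epochs number of passes over the training set.
#' @param lr Adam learning rate (> 0).
#' @param patience early-stop patience on validation loss (`Inf` disables).
#' @param seed integer seed controlling shuffling and augmentation.
#' @param augment optional [augmentation_policy()] applied to training
#'   patches on the fly.
#' @param verbose print per-epoch losses.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 500L, lr = 1e-3,
                         patience = Inf, seed = 1L, augment = NULL,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, patience = patience,
                 seed = as.integer(seed), augment = augment,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    g <- params[[i]]$grad
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    params[[i]]$val <- params[[i]]$val -
      lr * (st$m[[i]] / b1t) / (sqrt(st$v[[i]] / b2t) + eps)
  }
  st
}

# Stack a list of patch samples into batch arrays.
stack_batch <- function(samples) {
  ps <- dim(samples[[1]]$image_patch)
  n <- length(samples)
  x <- array(0, c(ps, 1L, n))
  g <- array(0, c(ps, 1L, n))
  lab <- numeric(n)
  for (i in seq_len(n)) {
    x[, , , 1L, i] <- samples[[i]]$image_patch
    g[, , , 1L, i] <- samples[[i]]$mask_patch
    lab[i] <- samples[[i]]$label
  }
  list(x = x, g = g, label = lab)
}

# Build the multi-task loss graph for one batch; returns the total node and
# the numeric per-term breakdown.
batch_loss <- function(model, ctx, batch, loss_cfg, training = TRUE) {
  out <- forward_unet(model, ctx, batch$x, training = training)
  p <- op_sigmoid(ctx, out$seg)
  terms <- list()
  w <- numeric(0)
  if (loss_cfg$dice > 0) {
    terms$dice <- op_dice_loss(ctx, p, batch$g, loss_cfg$smooth)
    w <- c(w, loss_cfg$dice)
  }
  if (loss_cfg$tversky_focal > 0) {
    terms$tversky_focal <- op_tversky_focal(
      ctx, p, batch$g, loss_cfg$tversky_alpha, loss_cfg$tversky_beta,
      loss_cfg$focal_gamma, loss_cfg$smooth)
    w <- c(w, loss_cfg$tversky_focal)
  }
  if (loss_cfg$cross_entropy > 0) {
    terms$cross_entropy <- op_bce_logits(ctx, out$seg, batch$g)
    w <- c(w, loss_cfg$cross_entropy)
  }
  seg <- op_scalar_comb(ctx, terms, w)
  has_aux <- loss_cfg$aux_weight > 0 && length(out$aux) > 0
  if (has_aux) {
    aux_terms <- lapply(out$aux, function(a) op_bce_logits(ctx, a, batch$label))
    aux <- op_scalar_comb(ctx, aux_terms,
                          rep(1 / length(aux_terms), length(aux_terms)))
    total <- op_scalar_comb(ctx, list(seg, aux),
                            c(0.5, 0.5 * loss_cfg$aux_weight))
    aux_val <- aux$val
  } else {
    total <- seg
    aux_val <- 0
  }
  list(total = total, seg = seg$val, aux = aux_val,
       terms = vapply(terms, function(t) t$val, 0))
}

#' Train the multi-task 3D U-Net
#'
#' Adam optimization of the combined segmentation + auxiliary loss, with
#' per-epoch loss history and best-validation checkpointing. Fully
#' deterministic given the seeds in the model and configuration. Aborts
#' with a diagnostic if the loss becomes non-finite.
#'
#' @param model a [build_model()] handle (modified in place and returned).
#' @param train_set a `patch_set` (see [build_dataset()]) used for
#'   gradient steps; must contain at least one positive patch.
#' @param val_set optional `patch_set` used for checkpoint selection.
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @return list with `model` (best-validation parameters restored) and
#'   `history` (data.frame: epoch, train_loss, seg_loss, aux_loss,
#'   val_loss).
#' @export
train_network <- function(model, train_set, val_set = NULL,
                          cfg = train_config(), loss_cfg = loss_config()) {
  stopifnot(inherits(model, "unet3d"), inherits(train_set, "patch_set"))
  if (!any(train_set$manifest$label == 1))
    stop("training set has no positive patch")
  samples <- train_set$samples
  n <- length(samples)
  adam <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     seg_loss = numeric(0), aux_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_state <- NULL
  bad_epochs <- 0
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_tot <- ep_seg <- ep_aux <- 0
      nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        bs <- samples[idx]
        if (!is.null(cfg$augment)) {
          pol <- cfg$augment
          for (j in seq_along(bs)) {
            pol$seed <- sample.int(2^30, 1)
            bs[[j]] <- augment(bs[[j]], pol)
          }
        }
        batch <- stack_batch(bs)
        ctx <- ag_ctx()
        bl <- batch_loss(model, ctx, batch, loss_cfg, training = TRUE)
        if (!is.finite(bl$total$val))
          stop(sprintf("training diverged at epoch %d (loss = %g)", ep,
                       bl$total$val))
        ag_zero_grads(model$params)
        ag_backward(ctx, bl$total)
        adam <- adam_step(model$params, adam, cfg$lr)
        ep_tot <- ep_tot + bl$total$val
        ep_seg <- ep_seg + bl$seg
        ep_aux <- ep_aux + bl$aux
        nb <- nb + 1
      }
      vl <- NA_real_
      if (!is.null(val_set) && length(val_set$samples) > 0) {
        vl <- evaluate_loss(model, val_set, loss_cfg)
        if (vl < best_val) {
          best_val <- vl
          best_state <- model_state(model)
          bad_epochs <- 0
        } else bad_epochs <- bad_epochs + 1
      }
      hist[nrow(hist) + 1, ] <- list(ep, ep_tot / nb, ep_seg / nb,
                                     ep_aux / nb, vl)
      if (cfg$verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_tot / nb,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
      if (bad_epochs > cfg$patience) break
    }
  })
  if (!is.null(best_state)) model_restore(model, best_state)
  list(model = model, history = hist)
}

#' Mean multi-task loss of a model over a patch set (no gradients)
#'
#' @param model a [build_model()] handle.
#' @param pset a `patch_set`.
#' @param loss_cfg a [loss_config()].
#' @param batch_size evaluation batch size.
#' @return mean total loss.
#' @export
evaluate_loss <- function(model, pset, loss_cfg = loss_config(),
                          batch_size = 8L) {
  n <- length(pset$samples)
  tot <- 0
  nb <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    batch <- stack_batch(pset$samples[idx])
    ctx <- ag_ctx()
    bl <- batch_loss(model, ctx, batch, loss_cfg, training = FALSE)
    tot <- tot + bl$total$val * length(idx)
    nb <- nb + length(idx)
  }
  tot / nb
}
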