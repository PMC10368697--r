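#' Whole-volume prediction by patch tiling along the skeleton
#'
#' Tiles patches over the vessel skeleton (stride configurable, default
#' non-overlapping), runs the network on each patch and averages per-voxel
#' probabilities over overlapping patches. Voxels never covered by a patch
#' get probability 0. The binary mask is obtained by thresholding the
#' averaged probabilities.
#'
#' @param model a [build_model()] handle.
#' @param img a preprocessed [image_volume()].
#' @param skeleton a [skeleton_voxels()] guiding patch placement.
#' @param patch_size integer triple; must be divisible by `2^depth`.
#' @param stride tile stride in voxels (default: the patch size, i.e. no
#'   overlap).
#' @param threshold binarization threshold (default 0.5).
#' @param batch_size patches per forward pass.
#' @return an object of class `volume_prediction`: list with
#'   `seg_probability` ([image_volume()] of probabilities), `mask`
#'   ([binary_mask()]), `patch_origins`, `aux_probability` (per tile, or
#'   `NULL`) and `threshold`.
#' @export
predict_volume <- function(model, img, skeleton,
                           patch_size = c(64, 64, 64), stride = NULL,
                           threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(model, "unet3d"), inherits(img, "image_volume"),
            inherits(skeleton, "skeleton_voxels"))
  ps <- as.integer(patch_size)
  stride <- as.integer(stride %||% ps)
  if (length(stride) == 1) stride <- rep(stride, 3)
  d <- dim(img$data)
  prob <- array(0, d)
  if (nrow(skeleton$coords) == 0) {
    warning("empty skeleton: returning an all-zero prediction")
    return(structure(list(
      seg_probability = image_volume(prob, img$spacing, img$origin),
      mask = binary_mask(array(FALSE, d), img$spacing, img$origin),
      patch_origins = matrix(integer(0), 0, 3),
      aux_probability = NULL, threshold = threshold),
      class = "volume_prediction"))
  }
  # snap each skeleton voxel's centered patch origin onto the stride grid,
  # then clamp so patches stay inside the (possibly padded) volume
  o_raw <- sweep(skeleton$coords, 2, ps %/% 2L, "-")
  o_snap <- sweep(o_raw, 2, stride, function(a, s) (a %/% s) * s) + 1L
  hi <- pmax(d - ps + 1L, 1L)
  o_snap <- pmin(pmax(o_snap, 1L), matrix(hi, nrow(o_snap), 3, byrow = TRUE))
  origins <- unique(o_snap)
  count <- array(0, d)
  aux <- numeric(0)
  for (start in seq(1, nrow(origins), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, nrow(origins))
    xb <- array(0, c(ps, length(idx)))
    for (j in seq_along(idx))
      xb[, , , j] <- crop_patch(img$data, origins[idx[j], ], ps, pad = 0)
    pr <- predict_patches(model, xb)
    for (j in seq_along(idx)) {
      o <- origins[idx[j], ]
      prob <- paste_patch(prob, pr$seg_probability[, , , j], o)
      count <- paste_patch(count, array(1, ps), o)
    }
    if (!is.null(pr$aux_probability)) aux <- c(aux, pr$aux_probability)
  }
  covered <- count > 0
  prob[covered] <- prob[covered] / count[covered]
  structure(list(
    seg_probability = image_volume(prob, img$spacing, img$origin),
    mask = binary_mask(array(prob >= threshold & covered, d), img$spacing,
                       img$origin),
    patch_origins = origins,
    aux_probability = if (length(aux)) aux else NULL,
    threshold = threshold),
    class = "volume_prediction")
}

#' @export
print.volume_prediction <- function(x, ...) {
  cat(sprintf("<volume_prediction: %d tiles, %d positive voxels>\n",
              nrow(x$patch_origins), sum(x$mask$data)))
  invisible(x)
}

#' Patch-level classification decisions
#'
#' Primary rule: a patch is predicted positive when its auxiliary
#' classifier probability exceeds 0.5. Fallback rule (for models without
#' auxiliary heads): positive when the predicted patch mask contains at
#' least `min_voxels` voxels above the segmentation threshold.
#'
#' @param model a [build_model()] handle.
#' @param pset a `patch_set`.
#' @param rule `"aux"` or `"mask"`; `"auto"` uses `"aux"` when the model
#'   has auxiliary heads.
#' @param min_voxels voxel count for the mask rule.
#' @param threshold segmentation probability threshold for the mask rule.
#' @param batch_size forward batch size.
#' @return data.frame with columns `label`, `prob` and `pred`.
#' @export
classify_patches <- function(model, pset, rule = c("auto", "aux", "mask"),
                             min_voxels = 5L, threshold = 0.5,
                             batch_size = 8L) {
  rule <- match.arg(rule)
  if (rule == "auto")
    rule <- if (length(model$net$aux) > 0) "aux" else "mask"
  n <- length(pset$samples)
  prob <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    ps <- dim(pset$samples[[idx[1]]]$image_patch)
    xb <- array(0, c(ps, length(idx)))
    for (j in seq_along(idx))
      xb[, , , j] <- pset$samples[[idx[j]]]$image_patch
    pr <- predict_patches(model, xb)
    prob[idx] <- if (rule == "aux") {
      if (is.null(pr$aux_probability))
        stop("model has no auxiliary head; use rule = \"mask\"")
      pr$aux_probability
    } else {
      vox <- apply(pr$seg_probability >= threshold, 4, sum)
      (vox + 0.5) / (vox + min_voxels)  # > 0.5 iff vox >= min_voxels
    }
  }
  data.frame(label = pset$manifest$label, prob = prob,
             pred = as.integer(prob > 0.5))
}
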