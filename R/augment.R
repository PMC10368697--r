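#' Patch augmentation policy
#'
#' The augmentation suite applied to training patches: horizontal and
#' vertical flips, zooming, Rician and Gaussian noise, rotation, blurring,
#' contrast and gamma correction. Geometric transforms are applied
#' identically to image and mask (nearest-neighbor for the mask, so it
#' stays binary); intensity transforms touch the image only. Parameter
#' ranges are conservative so small aneurysms are never destroyed.
#'
#' @param transforms character vector of enabled transforms, a subset of
#'   `c("flip_h", "flip_v", "zoom", "rician", "gaussian", "rotation",
#'   "blur", "contrast", "gamma")`.
#' @param flip_p per-axis flip probability.
#' @param zoom_range multiplicative zoom factor range.
#' @param rotation_deg maximum rotation per axis, degrees.
#' @param noise_sigma Gaussian/Rician noise sigma range, as a fraction of
#'   the patch intensity range.
#' @param blur_sigma_vox Gaussian blur sigma range in voxels.
#' @param contrast_range contrast scaling range (about the patch mean).
#' @param gamma_range gamma exponent range.
#' @param max_retries bounded retries when a geometric transform evicts the
#'   whole lesion from the patch.
#' @param seed integer seed; augmentation is deterministic given the policy.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(transforms = c("flip_h", "flip_v", "zoom",
                                               "rician", "gaussian",
                                               "rotation", "blur", "contrast",
                                               "gamma"),
                                flip_p = 0.5,
                                zoom_range = c(0.9, 1.1),
                                rotation_deg = 15,
                                noise_sigma = c(0.01, 0.05),
                                blur_sigma_vox = c(0.3, 0.8),
                                contrast_range = c(0.9, 1.1),
                                gamma_range = c(0.8, 1.2),
                                max_retries = 5L,
                                seed = 1L) {
  known <- c("flip_h", "flip_v", "zoom", "rician", "gaussian", "rotation",
             "blur", "contrast", "gamma")
  stopifnot(all(transforms %in% known))
  structure(list(transforms = transforms, flip_p = flip_p,
                 zoom_range = zoom_range, rotation_deg = rotation_deg,
                 noise_sigma = noise_sigma, blur_sigma_vox = blur_sigma_vox,
                 contrast_range = contrast_range, gamma_range = gamma_range,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

rotation_matrix_3d <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Augment one patch sample
#'
#' Applies the enabled transforms in a fixed order (geometric first, then
#' intensity). The label is recomputed from the transformed mask, so the
#' label-mask consistency invariant always holds. When zoom/rotation would
#' evict the whole lesion from a positive patch, the transform parameters
#' are re-drawn a bounded number of times, after which the geometric step is
#' skipped with a warning.
#'
#' @param sample a `patch_sample`.
#' @param policy an [augmentation_policy()].
#' @return augmented `patch_sample`.
#' @export
augment <- function(sample, policy = augmentation_policy()) {
  stopifnot(inherits(sample, "patch_sample"),
            inherits(policy, "augmentation_policy"))
  tr <- policy$transforms
  img <- sample$image_patch
  msk <- sample$mask_patch
  d <- dim(img)
  with_seed(policy$seed, {
    if ("flip_h" %in% tr && runif(1) < policy$flip_p) {
      img <- flip_axis(img, 1L)
      msk <- flip_axis(msk, 1L)
    }
    if ("flip_v" %in% tr && runif(1) < policy$flip_p) {
      img <- flip_axis(img, 2L)
      msk <- flip_axis(msk, 2L)
    }
    if (any(c("zoom", "rotation") %in% tr)) {
      had_lesion <- any(msk > 0)
      ok <- FALSE
      for (try in seq_len(policy$max_retries)) {
        s <- if ("zoom" %in% tr)
          runif(1, policy$zoom_range[1], policy$zoom_range[2]) else 1
        ang <- if ("rotation" %in% tr)
          runif(3, -policy$rotation_deg, policy$rotation_deg) * pi / 180
          else c(0, 0, 0)
        # output voxel -> input voxel about the patch center; sampling with
        # R^-1 and 1/s realizes a forward rotation by R and zoom by s
        A <- t(rotation_matrix_3d(ang[1], ang[2], ang[3])) / s
        ctr <- (d - 1) / 2
        tt <- ctr - A %*% ctr
        im2 <- affine_sample_cpp(img, d, d, A, tt, nearest = FALSE, oob = 0,
                                 clamp = FALSE)
        mk2 <- affine_sample_cpp(array(as.double(msk), d), d, d, A, tt,
                                 nearest = TRUE, oob = 0, clamp = FALSE)
        if (!had_lesion || any(mk2 > 0)) {
          img <- im2
          msk <- array(as.integer(mk2 > 0.5), d)
          ok <- TRUE
          break
        }
      }
      if (!ok && had_lesion)
        warning("zoom/rotation evicted the lesion in every retry; geometric step skipped")
    }
    rngI <- diff(range(img))
    if ("gaussian" %in% tr && rngI > 0) {
      sg <- runif(1, policy$noise_sigma[1], policy$noise_sigma[2]) * rngI
      img <- img + array(rnorm(length(img), 0, sg), d)
    }
    if ("rician" %in% tr && rngI > 0) {
      sg <- runif(1, policy$noise_sigma[1], policy$noise_sigma[2]) * rngI
      shift <- min(img)
      img <- sqrt((img - shift + array(rnorm(length(img), 0, sg), d))^2 +
                  array(rnorm(length(img), 0, sg), d)^2) + shift
    }
    if ("blur" %in% tr) {
      sg <- runif(1, policy$blur_sigma_vox[1], policy$blur_sigma_vox[2])
      img <- blur3d_cpp(img, d, sg)
    }
    if ("contrast" %in% tr) {
      f <- runif(1, policy$contrast_range[1], policy$contrast_range[2])
      m <- mean(img)
      img <- (img - m) * f + m
    }
    if ("gamma" %in% tr) {
      g <- runif(1, policy$gamma_range[1], policy$gamma_range[2])
      lo <- min(img)
      rg <- diff(range(img))
      if (rg > 0) img <- ((img - lo) / rg)^g * rg + lo
    }
  })
  new_patch_sample(array(img, d), array(as.integer(msk > 0), d),
                   sample$origin_vox, sample$case_id)
}
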