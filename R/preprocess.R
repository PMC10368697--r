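#' Preprocessing configuration
#'
#' Controls the normalization pipeline applied to angiographic volumes:
#' multiplicative bias-field correction, isotropic resampling, then
#' percentile clipping and z-score standardization. The correction step runs
#' on raw intensities and standardization comes last, because z-scoring
#' invalidates the multiplicative-field assumption of bias correction.
#'
#' @param clip_percentiles (low, high) percentiles for intensity clipping;
#'   default `c(0.5, 99.5)`.
#' @param target_spacing_mm isotropic target spacing; default 0.3 mm.
#' @param bias_correction logical, run bias-field correction.
#' @param brain_mask_strategy one of `"none"` (whole volume),
#'   `"threshold"` (simple intensity threshold) or `"file"` (an external
#'   mask on disk); stands in for trained skull-stripping models, which
#'   phantom data does not need.
#' @param brain_mask_file NIfTI path when `brain_mask_strategy = "file"`.
#' @param bias_degree polynomial degree of the fitted log-domain bias field.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_percentiles = c(0.5, 99.5),
                              target_spacing_mm = c(0.3, 0.3, 0.3),
                              bias_correction = TRUE,
                              brain_mask_strategy = c("none", "threshold",
                                                      "file"),
                              brain_mask_file = NULL,
                              bias_degree = 3L) {
  brain_mask_strategy <- match.arg(brain_mask_strategy)
  stopifnot(length(clip_percentiles) == 2,
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100,
            clip_percentiles[1] < clip_percentiles[2],
            all(target_spacing_mm > 0))
  structure(list(clip_percentiles = as.numeric(clip_percentiles),
                 target_spacing_mm = as.numeric(target_spacing_mm),
                 bias_correction = isTRUE(bias_correction),
                 brain_mask_strategy = brain_mask_strategy,
                 brain_mask_file = brain_mask_file,
                 bias_degree = as.integer(bias_degree)),
            class = "preprocess_config")
}

#' Clip intensities to percentiles and z-score standardize
#'
#' Values are clipped to the `[p_low, p_high]` percentile interval of the
#' input volume (percentiles use linear interpolation between order
#' statistics, `quantile()` type 7), then standardized with the mean and
#' standard deviation of the clipped volume, so the output has mean 0 and
#' standard deviation 1.
#'
#' @param img an [image_volume()].
#' @param cfg a [preprocess_config()].
#' @return a standardized [image_volume()].
#' @export
clip_and_standardize <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "image_volume"))
  v <- as.vector(img$data)
  if (length(unique(v)) < 2)
    stop("cannot standardize a constant image (sd undefined)")
  q <- quantile(v, cfg$clip_percentiles / 100, names = FALSE, type = 7)
  v <- pmin(pmax(v, q[1]), q[2])
  s <- sd(v)
  if (s == 0)
    stop("image is constant after clipping (sd undefined)")
  v <- (v - mean(v)) / s
  image_volume(array(v, dim(img$data)), img$spacing, img$origin)
}

#' Correct smooth multiplicative intensity inhomogeneity
#'
#' Estimates a smooth multiplicative bias field as a low-order polynomial in
#' the log domain, fitted to intensities inside `mask`, and divides it out.
#' The field is normalized to mean 1 inside the mask so the overall
#' intensity scale is preserved. If the correction would increase the
#' within-mask coefficient of variation the input is returned unchanged, so
#' the CV is guaranteed not to increase. Intended for raw magnitude images
#' (positive intensities); non-positive voxels are clamped to a small
#' positive value before the log transform.
#'
#' @param img an [image_volume()] with (mostly) positive intensities.
#' @param mask a [binary_mask()] delimiting the fit region (e.g. brain or
#'   vessel mask).
#' @param degree polynomial degree of the field (default 3).
#' @param max_fit_voxels subsample size for the polynomial fit.
#' @return bias-corrected [image_volume()].
#' @export
correct_bias <- function(img, mask, degree = 3L, max_fit_voxels = 20000L) {
  stopifnot(inherits(img, "image_volume"), inherits(mask, "binary_mask"))
  idx <- which(mask$data)
  if (length(idx) < 100) {
    warning("mask has fewer than 100 voxels; skipping bias correction")
    return(img)
  }
  d <- dim(img$data)
  take <- if (length(idx) > max_fit_voxels)
    idx[round(seq(1, length(idx), length.out = max_fit_voxels))] else idx
  co <- arrayInd(take, d)
  nx <- (co[, 1] - 1) / max(d[1] - 1, 1) * 2 - 1
  ny <- (co[, 2] - 1) / max(d[2] - 1, 1) * 2 - 1
  nz <- (co[, 3] - 1) / max(d[3] - 1, 1) * 2 - 1
  eps <- max(abs(img$data)) * 1e-6 + 1e-12
  y <- log(pmax(img$data[take], eps))
  Xd <- cbind(1, stats::poly(nx, ny, nz, degree = degree, raw = TRUE))
  fit <- lm.fit(Xd, y)
  # evaluate the field over the whole grid
  gx <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1) * 2 - 1
  gy <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1) * 2 - 1
  gz <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1) * 2 - 1
  ax <- rep(gx, times = d[2] * d[3])
  ay <- rep(rep(gy, each = d[1]), times = d[3])
  az <- rep(gz, each = d[1] * d[2])
  Xall <- cbind(1, stats::poly(ax, ay, az, degree = degree, raw = TRUE))
  logf <- as.vector(Xall %*% fit$coefficients)
  field <- array(exp(logf - mean(logf[idx])), d)
  out <- img$data / field
  cv <- function(x) sd(x) / mean(x)
  if (cv(out[idx]) > cv(img$data[idx])) {
    message("bias correction would increase within-mask CV; returning input")
    return(img)
  }
  image_volume(out, img$spacing, img$origin)
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation for image volumes, nearest-neighbor for binary
#' masks (so masks stay binary). Voxel centers are aligned so the physical
#' extent is preserved within one voxel per axis.
#'
#' @param img an [image_volume()] or [binary_mask()].
#' @param target_spacing_mm positive spacing triple.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(img, target_spacing_mm = c(0.3, 0.3, 0.3)) {
  UseMethod("resample_isotropic")
}

resample_grid <- function(d, spacing, target) {
  out_dim <- pmax(1L, as.integer(round(d * spacing / target)))
  ratio <- target / spacing
  # voxel-center mapping: p_in = (i + 0.5) * ratio - 0.5 (0-based)
  list(out_dim = out_dim, A = diag(ratio), t = 0.5 * ratio - 0.5)
}

#' @export
resample_isotropic.image_volume <- function(img,
                                            target_spacing_mm = c(0.3, 0.3, 0.3)) {
  stopifnot(all(target_spacing_mm > 0))
  if (isTRUE(all.equal(img$spacing, as.numeric(target_spacing_mm))))
    return(img)
  g <- resample_grid(dim(img$data), img$spacing, target_spacing_mm)
  arr <- affine_sample_cpp(img$data, dim(img$data), g$out_dim, g$A, g$t,
                           nearest = FALSE, oob = 0, clamp = TRUE)
  image_volume(arr, target_spacing_mm, img$origin)
}

#' @export
resample_isotropic.binary_mask <- function(img,
                                           target_spacing_mm = c(0.3, 0.3, 0.3)) {
  stopifnot(all(target_spacing_mm > 0))
  if (isTRUE(all.equal(img$spacing, as.numeric(target_spacing_mm))))
    return(img)
  g <- resample_grid(dim(img$data), img$spacing, target_spacing_mm)
  arr <- affine_sample_cpp(array(as.double(img$data), dim(img$data)),
                           dim(img$data), g$out_dim, g$A, g$t,
                           nearest = TRUE, oob = 0, clamp = TRUE)
  binary_mask(array(arr > 0.5, dim(arr)), target_spacing_mm, img$origin)
}

#' Compute a brain mask
#'
#' Pluggable stand-in for skull stripping: `"none"` returns a full mask,
#' `"threshold"` keeps voxels above a threshold (default: the volume mean),
#' `"file"` reads an external mask and resamples it to the image grid if
#' needed.
#'
#' @param img an [image_volume()].
#' @param cfg a [preprocess_config()].
#' @param threshold optional numeric threshold for the `"threshold"`
#'   strategy.
#' @return a [binary_mask()] on the image grid.
#' @export
compute_brain_mask <- function(img, cfg = preprocess_config(),
                               threshold = NULL) {
  d <- dim(img$data)
  switch(cfg$brain_mask_strategy,
    none = binary_mask(array(TRUE, d), img$spacing, img$origin),
    threshold = {
      thr <- threshold %||% mean(img$data)
      binary_mask(array(img$data > thr, d), img$spacing, img$origin)
    },
    file = {
      m <- read_volume(cfg$brain_mask_file, mask = TRUE)
      if (!identical(dim(m$data), d))
        m <- resample_isotropic(m, img$spacing)
      m
    })
}

#' Run the full preprocessing pipeline on one volume
#'
#' Order of operations: bias correction (on raw intensities), isotropic
#' resampling, then percentile clipping and z-score standardization. The
#' pipeline is deterministic.
#'
#' @param img an [image_volume()].
#' @param cfg a [preprocess_config()].
#' @param mask optional [binary_mask()] used for the bias fit; defaults to
#'   the configured brain-mask strategy.
#' @return preprocessed [image_volume()].
#' @export
preprocess_volume <- function(img, cfg = preprocess_config(), mask = NULL) {
  if (cfg$bias_correction) {
    m <- mask %||% compute_brain_mask(img, cfg)
    img <- correct_bias(img, m, degree = cfg$bias_degree)
  }
  img <- resample_isotropic(img, cfg$target_spacing_mm)
  clip_and_standardize(img, cfg)
}
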