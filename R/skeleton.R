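#' Skeletonization configuration
#'
#' Parameters of the five-step vessel skeletonization: intensity threshold,
#' connected-component size filter, intensity-gated region growing,
#' morphological closing, and topology-preserving iterative thinning under
#' foreground 26-connectivity / background 6-connectivity.
#'
#' @param threshold_strategy `"percentile"` (threshold at a percentile of
#'   in-mask intensities), `"fixed"` (absolute value) or `"auto"` (midpoint
#'   between the two intensity modes found by 2-means, suited to bimodal
#'   angiographic and phantom intensity histograms).
#' @param threshold_value the percentile (default 99) or fixed value,
#'   depending on strategy; ignored for `"auto"`.
#' @param min_component_voxels components smaller than this are discarded;
#'   default 3000 voxels, defined at 0.3 mm spacing and rescaled by
#'   `(0.3 / spacing)^3` when the data spacing differs, so the physical size
#'   cutoff is spacing-invariant.
#' @param closing_radius_vox ball radius (voxels) of the morphological
#'   closing; 0 disables it.
#' @param grow_tolerance region growing accepts 26-neighbors down to
#'   `threshold - tolerance * |threshold|`; default 0.1.
#' @return an object of class `skeleton_config`.
#' @export
skeleton_config <- function(threshold_strategy = c("percentile", "fixed",
                                                   "auto"),
                            threshold_value = 99,
                            min_component_voxels = 3000L,
                            closing_radius_vox = 1L,
                            grow_tolerance = 0.1) {
  threshold_strategy <- match.arg(threshold_strategy)
  stopifnot(min_component_voxels >= 0, closing_radius_vox >= 0,
            grow_tolerance >= 0)
  structure(list(threshold_strategy = threshold_strategy,
                 threshold_value = threshold_value,
                 min_component_voxels = as.integer(min_component_voxels),
                 closing_radius_vox = as.integer(closing_radius_vox),
                 grow_tolerance = grow_tolerance),
            class = "skeleton_config")
}

#' Threshold an image into a vessel candidate mask
#'
#' @param img an [image_volume()] (typically preprocessed).
#' @param cfg a [skeleton_config()].
#' @param brain_mask optional [binary_mask()]; percentile/auto thresholds
#'   are computed from in-mask intensities only.
#' @return a [binary_mask()] with attribute `"threshold"` holding the
#'   resolved threshold value. Warns when the threshold falls outside the
#'   data range (empty or full mask).
#' @export
binarize_vessels <- function(img, cfg = skeleton_config(),
                             brain_mask = NULL) {
  stopifnot(inherits(img, "image_volume"))
  v <- if (is.null(brain_mask)) as.vector(img$data)
       else img$data[brain_mask$data]
  thr <- switch(cfg$threshold_strategy,
    fixed = cfg$threshold_value,
    percentile = quantile(v, cfg$threshold_value / 100, names = FALSE),
    auto = {
      km <- kmeans(v, centers = range(v), iter.max = 50)
      mean(km$centers)
    })
  if (thr > max(img$data) || thr <= min(img$data))
    warning(sprintf("threshold %.4g lies outside the data range [%.4g, %.4g]",
                    thr, min(img$data), max(img$data)))
  m <- array(img$data >= thr, dim(img$data))
  out <- binary_mask(m, img$spacing, img$origin)
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Keep only large 26-connected components
#'
#' @param mask a [binary_mask()].
#' @param min_voxels minimum component size in voxels; components smaller
#'   than this are removed. `0` is the identity.
#' @return filtered [binary_mask()].
#' @export
filter_components <- function(mask, min_voxels = 3000L) {
  stopifnot(inherits(mask, "binary_mask"), min_voxels >= 0)
  if (min_voxels == 0 || !any(mask$data)) return(mask)
  lab <- label26_cpp(mask$data, dim(mask$data))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  m <- array(lab %in% keep & lab > 0, dim(mask$data))
  out <- binary_mask(m, mask$spacing, mask$origin)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Grow a mask into adjacent above-threshold voxels
#'
#' Iteratively adds 26-neighbors of the current mask whose intensity is at
#' least the tolerance-relaxed threshold, until a fixpoint is reached. The
#' output always contains the input and never exceeds the superset mask
#' `img >= relaxed_threshold`.
#'
#' @param mask a nonempty [binary_mask()] (the seed).
#' @param img the [image_volume()] the mask was derived from.
#' @param threshold the vessel threshold; defaults to the `"threshold"`
#'   attribute of `mask` if present.
#' @param tolerance relative relaxation: neighbors are accepted down to
#'   `threshold - tolerance * |threshold|`.
#' @return grown [binary_mask()].
#' @export
region_grow <- function(mask, img, threshold = NULL, tolerance = 0.1) {
  stopifnot(inherits(mask, "binary_mask"), inherits(img, "image_volume"))
  thr <- threshold %||% attr(mask, "threshold")
  if (is.null(thr)) stop("no threshold supplied and mask carries none")
  relaxed <- thr - tolerance * abs(thr)
  m <- region_grow_cpp(mask$data, dim(mask$data), img$data, relaxed)
  out <- binary_mask(m, mask$spacing, mask$origin)
  attr(out, "threshold") <- thr
  out
}

#' Morphological closing with a ball structuring element
#'
#' Dilation followed by erosion; fills holes and gaps up to the ball
#' radius. Voxels outside the volume count as background for the dilation
#' and as foreground for the erosion, so the closing never eats into the
#' volume border. Radius 0 is the identity; closing is idempotent.
#'
#' @param mask a [binary_mask()].
#' @param radius_vox ball radius in voxels.
#' @return closed [binary_mask()].
#' @export
close_holes <- function(mask, radius_vox = 1L) {
  stopifnot(inherits(mask, "binary_mask"), radius_vox >= 0)
  if (radius_vox == 0) return(mask)
  d <- dilate_ball_cpp(mask$data, dim(mask$data), radius_vox)
  e <- erode_ball_cpp(d, dim(mask$data), radius_vox, border_fg = TRUE)
  out <- binary_mask(e, mask$spacing, mask$origin)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Thin a binary mask to its centerline skeleton
#'
#' Topology-preserving 3D thinning: simple voxels (removable without
#' changing the object's topology, tested under foreground 26-connectivity
#' and background 6-connectivity) are deleted sequentially in raster order
#' within six directional sub-iterations, until no deletable voxel remains.
#' Curve endpoints (voxels with at most one foreground 26-neighbor) are
#' preserved, so 1-voxel-wide lines are returned unchanged. The result is a
#' subset of the input with the same number of 26-connected components, and
#' thinning its own output is the identity.
#'
#' @param mask a [binary_mask()] (may be empty).
#' @return a [skeleton_voxels()] object.
#' @export
thin_to_skeleton <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sk <- thin3d_cpp(mask$data, dim(mask$data))
  skeleton_voxels(which(sk, arr.ind = TRUE), dim(mask$data), mask$spacing)
}

#' Full five-step vessel skeletonization
#'
#' Threshold, size-filter 26-connected components (cutoff rescaled by
#' `(0.3 / spacing)^3` so it stays a physical-size filter), region-grow,
#' morphologically close, and thin to a centerline skeleton.
#'
#' @param img a preprocessed [image_volume()].
#' @param cfg a [skeleton_config()].
#' @param brain_mask optional [binary_mask()] restricting threshold
#'   estimation.
#' @return a list with elements `mask` (the final vessel [binary_mask()]),
#'   `skeleton` (a [skeleton_voxels()]) and `threshold`.
#' @export
vessel_skeleton <- function(img, cfg = skeleton_config(), brain_mask = NULL) {
  m <- binarize_vessels(img, cfg, brain_mask)
  scale <- prod(0.3 / img$spacing)
  m <- filter_components(m, as.integer(round(cfg$min_component_voxels * scale)))
  if (any(m$data))
    m <- region_grow(m, img, tolerance = cfg$grow_tolerance)
  m <- close_holes(m, cfg$closing_radius_vox)
  list(mask = m, skeleton = thin_to_skeleton(m),
       threshold = attr(m, "threshold"))
}
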