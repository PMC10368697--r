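#' 3D image volume with physical spacing
#'
#' Carrier for angiographic volumes and synthetic phantoms: a 3D numeric
#' array plus voxel spacing (mm) and a world origin. Voxel indices are
#' 1-based in R code and follow (x, y, z) array order.
#'
#' @param data 3D numeric array.
#' @param spacing_mm positive numeric triple, voxel spacing in mm.
#' @param origin_mm numeric triple, world coordinate of voxel (1,1,1).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing_mm) == 3, all(spacing_mm > 0))
  structure(list(data = data, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "image_volume")
}

#' Binary mask aligned to an image volume
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing_mm positive numeric triple.
#' @param origin_mm numeric triple.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.logical(data)) {
    v <- unique(as.vector(data))
    if (!all(v %in% c(0, 1)))
      stop("mask values must lie in {0, 1}")
    data <- array(data > 0, dim(data))
  }
  structure(list(data = data, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, spacing %s mm, %d foreground voxels>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' Read a NIfTI file as an image volume or binary mask
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, return a [binary_mask()] (values are binarized at
#'   0.5).
#' @return an [image_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (mask) binary_mask(array(arr > 0.5, dim(arr)), sp)
  else image_volume(arr, sp)
}

#' Write an image volume or binary mask to NIfTI
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (is.logical(vol$data)) array(as.integer(vol$data), dim(vol$data))
         else vol$data
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Set of skeleton voxel coordinates
#'
#' Thin centerline voxels extracted from a vessel mask, stored as 1-based
#' (x, y, z) index triples together with the source grid shape.
#'
#' @param coords integer matrix with 3 columns (1-based voxel indices).
#' @param shape integer triple, shape of the source mask.
#' @param spacing_mm voxel spacing of the source mask.
#' @return an object of class `skeleton_voxels`.
#' @export
skeleton_voxels <- function(coords, shape, spacing_mm = c(1, 1, 1)) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(coords) > 0) {
    stopifnot(all(coords >= 1), all(t(coords) <= shape))
  }
  structure(list(coords = coords, shape = as.integer(shape),
                 spacing = as.numeric(spacing_mm)),
            class = "skeleton_voxels")
}

#' @export
print.skeleton_voxels <- function(x, ...) {
  cat(sprintf("<skeleton_voxels: %d voxels in %s grid>\n", nrow(x$coords),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Rebuild the logical array form of a skeleton
#'
#' @param skel a [skeleton_voxels()] object.
#' @return 3D logical array.
#' @export
skeleton_mask <- function(skel) {
  m <- array(FALSE, skel$shape)
  if (nrow(skel$coords) > 0) m[skel$coords] <- TRUE
  m
}

#' Export skeleton coordinates as CSV
#'
#' @param skel a [skeleton_voxels()] object.
#' @param path output CSV path with columns x, y, z (1-based voxel indices).
#' @export
write_skeleton_csv <- function(skel, path) {
  write.csv(as.data.frame(skel$coords), path, row.names = FALSE)
  invisible(path)
}
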