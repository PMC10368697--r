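#' @useDynLib skelpatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd lm.fit predict kmeans median
#' @importFrom utils write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(k)) %% 2147483629)
}

#' Crop a patch from a 3D array with zero padding outside the volume
#'
#' @param arr 3D array.
#' @param origin integer triple, 1-based index of the patch corner; may lie
#'   outside the array, in which case the patch is padded with `pad`.
#' @param size integer triple, patch shape.
#' @param pad fill value for out-of-volume voxels.
#' @return array of shape `size`.
#' @export
crop_patch <- function(arr, origin, size, pad = 0) {
  d <- dim(arr)
  stopifnot(length(d) == 3, length(origin) == 3, length(size) == 3)
  origin <- as.integer(origin)
  size <- as.integer(size)
  out <- array(pad, size)
  lo_src <- pmax(origin, 1L)
  hi_src <- pmin(origin + size - 1L, d)
  if (any(lo_src > hi_src)) return(out)
  lo_dst <- lo_src - origin + 1L
  hi_dst <- hi_src - origin + 1L
  out[lo_dst[1]:hi_dst[1], lo_dst[2]:hi_dst[2], lo_dst[3]:hi_dst[3]] <-
    arr[lo_src[1]:hi_src[1], lo_src[2]:hi_src[2], lo_src[3]:hi_src[3]]
  out
}

# Paste a patch-shaped array of values into an accumulator, clipping to the
# volume; used by tiled inference.
paste_patch <- function(acc, patch, origin) {
  d <- dim(acc)
  size <- dim(patch)
  lo_src <- pmax(origin, 1L)
  hi_src <- pmin(origin + size - 1L, d)
  if (any(lo_src > hi_src)) return(acc)
  lo_dst <- lo_src - origin + 1L
  hi_dst <- hi_src - origin + 1L
  acc[lo_src[1]:hi_src[1], lo_src[2]:hi_src[2], lo_src[3]:hi_src[3]] <-
    acc[lo_src[1]:hi_src[1], lo_src[2]:hi_src[2], lo_src[3]:hi_src[3]] +
    patch[lo_dst[1]:hi_dst[1], lo_dst[2]:hi_dst[2], lo_dst[3]:hi_dst[3]]
  acc
}
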