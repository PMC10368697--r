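#' Patch sampling plan
#'
#' Controls extraction of 3D patches along the vessel skeleton. Positive
#' patches are drawn "non-centered" around each aneurysm: the patch origin
#' is uniform over all origins whose patch fully contains the aneurysm
#' component. Negative patches are centered on skeleton voxels at a safe
#' distance from any aneurysm. The dataset enforces an exact
#' aneurysm : normal ratio of 1 : `ratio` with `ratio` in 1..5.
#'
#' @param patch_size integer triple; default `c(64, 64, 64)`.
#' @param ratio integer in 1..5: number of normal patches per aneurysm
#'   patch.
#' @param n_positive_per_aneurysm positive patches drawn per aneurysm
#'   component; default 10.
#' @param min_negative_distance_mm exclusion radius around aneurysm voxels
#'   for negative patch centers; default 5 mm.
#' @param per_case if `TRUE` the ratio is enforced within each case instead
#'   of globally over the cohort (the default).
#' @param seed integer seed; sampling is deterministic given the plan.
#' @return an object of class `sampling_plan`.
#' @export
sampling_plan <- function(patch_size = c(64, 64, 64),
                          ratio = 2L,
                          n_positive_per_aneurysm = 10L,
                          min_negative_distance_mm = 5,
                          per_case = FALSE,
                          seed = 1L) {
  stopifnot(length(patch_size) == 3, all(patch_size >= 1),
            ratio >= 1, ratio <= 5,
            n_positive_per_aneurysm >= 0, min_negative_distance_mm >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 ratio = as.integer(ratio),
                 n_positive_per_aneurysm = as.integer(n_positive_per_aneurysm),
                 min_negative_distance_mm = min_negative_distance_mm,
                 per_case = isTRUE(per_case),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

new_patch_sample <- function(image_patch, mask_patch, origin, case_id) {
  structure(list(image_patch = image_patch,
                 mask_patch = mask_patch,
                 label = as.integer(any(mask_patch > 0)),
                 origin_vox = as.integer(origin),
                 case_id = case_id),
            class = "patch_sample")
}

# Admissible origin box for a component bounding box: all origins whose
# patch [o, o + ps - 1] contains [lo, hi].
admissible_origin_range <- function(lo, hi, patch_size) {
  cbind(from = hi - patch_size + 1L, to = lo)
}

#' Sample positive patches around each aneurysm
#'
#' For every 26-connected aneurysm component, draws
#' `plan$n_positive_per_aneurysm` patches whose origins are uniform over the
#' set of origins that fully contain that component, so the whole lesion
#' mask is always inside the patch (non-centered sampling). Patches that
#' extend beyond the volume are zero-padded.
#'
#' @param img an [image_volume()].
#' @param aneurysm_mask a nonempty [binary_mask()] on the same grid.
#' @param plan a [sampling_plan()].
#' @param case_id identifier recorded in each sample.
#' @param .seed RNG seed override (defaults to `plan$seed`).
#' @return list of `patch_sample` objects, all with label 1.
#' @export
sample_positive_patches <- function(img, aneurysm_mask, plan = sampling_plan(),
                                    case_id = "case", .seed = NULL) {
  stopifnot(inherits(img, "image_volume"), inherits(aneurysm_mask, "binary_mask"))
  if (!any(aneurysm_mask$data)) stop("aneurysm mask is empty")
  ps <- plan$patch_size
  lab <- label26_cpp(aneurysm_mask$data, dim(aneurysm_mask$data))
  ncomp <- attr(lab, "n_components")
  out <- list()
  with_seed(.seed %||% plan$seed, {
    for (k in seq_len(ncomp)) {
      co <- which(lab == k, arr.ind = TRUE)
      lo <- apply(co, 2, min)
      hi <- apply(co, 2, max)
      ext <- hi - lo + 1L
      if (any(ext > ps))
        stop(sprintf(
          "aneurysm component %d extent %s exceeds patch size %s",
          k, paste(ext, collapse = "x"), paste(ps, collapse = "x")))
      rng <- admissible_origin_range(lo, hi, ps)
      for (i in seq_len(plan$n_positive_per_aneurysm)) {
        o <- rng[, "from"] +
          vapply(rng[, "to"] - rng[, "from"] + 1L,
                 function(n) sample.int(n, 1L) - 1L, integer(1))
        out[[length(out) + 1]] <- new_patch_sample(
          crop_patch(img$data, o, ps, pad = 0),
          crop_patch(array(as.integer(aneurysm_mask$data),
                           dim(aneurysm_mask$data)), o, ps, pad = 0L),
          o, case_id)
      }
    }
  })
  out
}

#' Sample negative (aneurysm-free) patches along the skeleton
#'
#' Draws patches centered on skeleton voxels lying at least
#' `plan$min_negative_distance_mm` from any aneurysm voxel; origins are
#' clamped to the volume bounds. Every returned patch is verified
#' aneurysm-free (all-zero mask, label 0). If fewer admissible skeleton
#' voxels exist than requested, all of them are returned with a warning.
#'
#' @param img an [image_volume()].
#' @param skeleton a nonempty [skeleton_voxels()].
#' @param aneurysm_mask a [binary_mask()] (may be empty).
#' @param plan a [sampling_plan()].
#' @param n_needed number of negatives to draw.
#' @param case_id identifier recorded in each sample.
#' @param .seed RNG seed override (defaults to `plan$seed`).
#' @return list of `patch_sample` objects, all with label 0.
#' @export
sample_negative_patches <- function(img, skeleton, aneurysm_mask,
                                    plan = sampling_plan(), n_needed,
                                    case_id = "case", .seed = NULL) {
  stopifnot(inherits(skeleton, "skeleton_voxels"))
  if (nrow(skeleton$coords) == 0) stop("skeleton is empty")
  if (n_needed == 0) return(list())
  ps <- plan$patch_size
  d <- dim(img$data)
  centers <- skeleton$coords
  if (any(aneurysm_mask$data)) {
    an <- which(aneurysm_mask$data, arr.ind = TRUE)
    dist <- min_dist_mm_cpp(centers - 1, an - 1, img$spacing)
    centers <- centers[dist >= plan$min_negative_distance_mm, , drop = FALSE]
  }
  amask <- array(as.integer(aneurysm_mask$data), dim(aneurysm_mask$data))
  out <- list()
  with_seed(.seed %||% plan$seed, {
    ord <- sample.int(nrow(centers))
    for (i in ord) {
      if (length(out) >= n_needed) break
      o <- centers[i, ] - ps %/% 2
      o <- pmin(pmax(o, 1L), pmax(d - ps + 1L, 1L))
      mp <- crop_patch(amask, o, ps, pad = 0L)
      if (any(mp > 0)) next  # a large aneurysm can reach past the exclusion radius
      out[[length(out) + 1]] <- new_patch_sample(
        crop_patch(img$data, o, ps, pad = 0), mp, o, case_id)
    }
  })
  if (length(out) < n_needed)
    warning(sprintf("only %d of %d requested negative patches are admissible",
                    length(out), n_needed))
  out
}

#' Build a ratio-controlled patch dataset from a case cohort
#'
#' Extracts positive patches for every aneurysm and exactly
#' `plan$ratio` times as many negative patches (enforced globally over the
#' cohort, or per case when `plan$per_case`). Per-case provenance is kept in
#' the manifest for case-level evaluation. Deterministic given `plan$seed`.
#'
#' @param cases list of prepared cases; each case is a list with elements
#'   `image` ([image_volume()]), `aneurysm_mask` ([binary_mask()]),
#'   `skeleton` ([skeleton_voxels()]) and `case_id`.
#' @param plan a [sampling_plan()].
#' @param require_positives error when the whole cohort has no aneurysm
#'   (the default, as for training datasets).
#' @param strict_ratio error when the cohort cannot supply the full
#'   negative quota (the default, preserving the exact-ratio invariant for
#'   training sets); when `FALSE`, a warning is issued and all admissible
#'   negatives are used, which suits small validation/test splits.
#' @return an object of class `patch_set`: list with `samples` (list of
#'   `patch_sample`), `manifest` (data.frame with case_id, origin, label)
#'   and `plan`.
#' @export
build_dataset <- function(cases, plan = sampling_plan(),
                          require_positives = TRUE, strict_ratio = TRUE) {
  # per-case seeds derive from the case identifier (not the list position)
  # and the negative quota is allocated in sorted-identifier order, so the
  # sampled multiset of patches is invariant under case-order shuffling
  case_hash <- function(id) {
    v <- utf8ToInt(as.character(id))
    as.integer(sum(v * seq_along(v)) %% 1000003L)
  }
  ord <- order(vapply(cases, function(cs) as.character(cs$case_id), ""))
  pos <- list()
  per_case_pos <- integer(length(cases))
  for (ci in ord) {
    cs <- cases[[ci]]
    if (any(cs$aneurysm_mask$data)) {
      p <- sample_positive_patches(
        cs$image, cs$aneurysm_mask, plan, case_id = cs$case_id,
        .seed = derive_seed(plan$seed, 2L * case_hash(cs$case_id)))
      per_case_pos[ci] <- length(p)
      pos <- c(pos, p)
    }
  }
  if (length(pos) == 0 && require_positives)
    stop("no positive patches in the cohort; cannot build a training dataset")
  n_neg_total <- plan$ratio * length(pos)
  neg <- list()
  if (n_neg_total > 0) {
    quota <- integer(length(cases))
    if (plan$per_case) {
      quota <- plan$ratio * per_case_pos
    } else {
      quota[ord] <- n_neg_total %/% length(cases)
      extra <- n_neg_total - sum(quota)
      if (extra > 0)
        quota[ord[seq_len(extra)]] <- quota[ord[seq_len(extra)]] + 1L
    }
    shortfall <- 0L
    for (ci in ord) {
      cs <- cases[[ci]]
      want <- quota[ci] + shortfall
      if (want == 0) next
      got <- suppressWarnings(sample_negative_patches(
        cs$image, cs$skeleton, cs$aneurysm_mask, plan, want,
        case_id = cs$case_id,
        .seed = derive_seed(plan$seed, 2L * case_hash(cs$case_id) + 1L)))
      shortfall <- want - length(got)
      neg <- c(neg, got)
    }
    if (length(neg) < n_neg_total) {
      msg <- sprintf(
        "cohort supports only %d of %d negative patches required by ratio 1:%d",
        length(neg), n_neg_total, plan$ratio)
      if (strict_ratio) stop(msg) else warning(msg)
    }
  }
  samples <- c(pos, neg)
  manifest <- data.frame(
    case_id = vapply(samples, function(s) as.character(s$case_id), ""),
    origin_x = vapply(samples, function(s) s$origin_vox[1], 0L),
    origin_y = vapply(samples, function(s) s$origin_vox[2], 0L),
    origin_z = vapply(samples, function(s) s$origin_vox[3], 0L),
    label = vapply(samples, function(s) s$label, 0L),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, manifest = manifest, plan = plan),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d patches (%d aneurysm, %d normal), size %s>\n",
              nrow(x$manifest), sum(x$manifest$label == 1),
              sum(x$manifest$label == 0),
              paste(x$plan$patch_size, collapse = "x")))
  invisible(x)
}

#' Persist a patch set to a directory
#'
#' Writes a manifest CSV and one NIfTI pair (image/mask) per patch.
#'
#' @param pset a `patch_set`.
#' @param dir output directory.
#' @export
write_patch_set <- function(pset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(pset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (i in seq_along(pset$samples)) {
    s <- pset$samples[[i]]
    write_volume(image_volume(s$image_patch),
                 file.path(dir, sprintf("patch_%05d_image.nii.gz", i)))
    write_volume(binary_mask(array(s$mask_patch > 0, dim(s$mask_patch))),
                 file.path(dir, sprintf("patch_%05d_mask.nii.gz", i)))
  }
  invisible(dir)
}
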