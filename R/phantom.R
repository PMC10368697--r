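#' Specification of a synthetic TOF-MRA phantom
#'
#' Describes a synthetic angiographic volume: bright tubular vessels on a
#' dark background, ellipsoidal aneurysm bulges attached to vessel walls, a
#' smooth multiplicative bias field and Rician magnitude noise. Defaults
#' mirror clinical TOF-MRA of the circle of Willis: sub-millimetre isotropic
#' voxels (0.3 mm), vessel radii 0.5-3 mm and aneurysm diameters 1.8-32.6 mm
#' with a size mix dominated by very small (< 5 mm) lesions.
#'
#' @param volume_shape integer triple, grid shape in voxels.
#' @param spacing_mm positive triple, voxel spacing in mm.
#' @param n_vessels number of vessels.
#' @param vessel_radius_range_mm (lo, hi) vessel radius range in mm.
#' @param n_aneurysms number of aneurysm bulges.
#' @param aneurysm_diameter_range_mm (lo, hi) aneurysm diameter range in mm;
#'   the upper end is truncated so that a bulge can fit inside the volume.
#' @param vessel_intensity mean foreground intensity (arbitrary units).
#' @param background_intensity mean background intensity; must be lower than
#'   `vessel_intensity`.
#' @param rician_sigma Rician noise scale (0 disables noise).
#' @param bias_amplitude half-range of the multiplicative bias field in
#'   `[0, 1)`; the field spans `[1 - a, 1 + a]`.
#' @param vessel_style `"spline"` for smooth random cubic-spline centerlines
#'   or `"straight"` for axis-aligned straight tubes spanning the volume.
#' @param seed integer seed; phantom generation is fully deterministic given
#'   the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(128, 128, 128),
                         spacing_mm = c(0.3, 0.3, 0.3),
                         n_vessels = 3,
                         vessel_radius_range_mm = c(0.5, 3),
                         n_aneurysms = 1,
                         aneurysm_diameter_range_mm = c(1.8, 32.6),
                         vessel_intensity = 300,
                         background_intensity = 50,
                         rician_sigma = 15,
                         bias_amplitude = 0.2,
                         vessel_style = c("spline", "straight"),
                         seed = 1L) {
  vessel_style <- match.arg(vessel_style)
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            n_vessels >= 0, n_aneurysms >= 0,
            length(vessel_radius_range_mm) == 2,
            vessel_radius_range_mm[1] <= vessel_radius_range_mm[2],
            vessel_radius_range_mm[1] > 0,
            length(aneurysm_diameter_range_mm) == 2,
            aneurysm_diameter_range_mm[1] <= aneurysm_diameter_range_mm[2],
            vessel_intensity > background_intensity,
            rician_sigma >= 0,
            bias_amplitude >= 0, bias_amplitude < 1)
  extent_mm <- volume_shape * spacing_mm
  # largest bulge that can sit fully inside the volume, with a small margin
  fit_mm <- 0.8 * min(extent_mm)
  rng <- aneurysm_diameter_range_mm
  if (n_aneurysms > 0 && rng[1] > fit_mm)
    stop(sprintf(paste0("aneurysm diameter %.1f mm cannot fit inside a ",
                        "%.1f x %.1f x %.1f mm volume"),
                 rng[1], extent_mm[1], extent_mm[2], extent_mm[3]))
  rng[2] <- min(rng[2], fit_mm)
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range_mm = as.numeric(vessel_radius_range_mm),
                 n_aneurysms = as.integer(n_aneurysms),
                 aneurysm_diameter_range_mm = as.numeric(rng),
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 rician_sigma = rician_sigma,
                 bias_amplitude = bias_amplitude,
                 vessel_style = vessel_style,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Draw aneurysm diameters from the clinical size mixture
#'
#' Sizes are drawn from three strata - very small (< 5 mm), small (5-10 mm)
#' and large (> 10 mm) - with weights 130 : 21 : 3, the stratum counts of a
#' 154-patient aneurysm cohort; within a stratum the diameter is uniform.
#' All diameters fall in the 1.8-32.6 mm clinical range.
#'
#' @param n number of diameters to draw.
#' @param seed integer seed.
#' @return numeric vector of `n` diameters in mm.
#' @export
sample_size_mix <- function(n, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    stratum <- sample.int(3, n, replace = TRUE, prob = c(130, 21, 3) / 154)
    lo <- c(1.8, 5, 10)[stratum]
    hi <- c(5, 10, 32.6)[stratum]
    runif(n, lo, hi)
  })
}

# Sample a smooth centerline polyline (mm coordinates) for one vessel.
vessel_centerline <- function(extent_mm, margin_mm, style, n_samples = 800) {
  if (style == "straight") {
    axis <- sample.int(3, 1)
    p <- runif(3, margin_mm, extent_mm - margin_mm)
    tgrid <- seq(0, extent_mm[axis], length.out = n_samples)
    pts <- matrix(rep(p, each = n_samples), ncol = 3)
    pts[, axis] <- tgrid
    return(pts)
  }
  k <- 5L
  ctrl <- cbind(runif(k, margin_mm[1], extent_mm[1] - margin_mm[1]),
                runif(k, margin_mm[2], extent_mm[2] - margin_mm[2]),
                runif(k, margin_mm[3], extent_mm[3] - margin_mm[3]))
  # order control points along a random direction so the tube does not loop
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  ctrl <- ctrl[order(ctrl %*% u), , drop = FALSE]
  tt <- seq_len(k)
  ts <- seq(1, k, length.out = n_samples)
  cbind(stats::spline(tt, ctrl[, 1], xout = ts)$y,
        stats::spline(tt, ctrl[, 2], xout = ts)$y,
        stats::spline(tt, ctrl[, 3], xout = ts)$y)
}

# Smooth random low-order (quadratic) multiplicative field in [1-a, 1+a].
random_bias_field <- function(dims, amplitude) {
  if (amplitude <= 0) return(array(1, dims))
  gx <- rep(seq(-1, 1, length.out = dims[1]), times = dims[2] * dims[3])
  gy <- rep(rep(seq(-1, 1, length.out = dims[2]), each = dims[1]),
            times = dims[3])
  gz <- rep(seq(-1, 1, length.out = dims[3]), each = dims[1] * dims[2])
  co <- rnorm(9)
  f <- co[1] * gx + co[2] * gy + co[3] * gz +
    co[4] * gx^2 + co[5] * gy^2 + co[6] * gz^2 +
    co[7] * gx * gy + co[8] * gx * gz + co[9] * gy * gz
  f <- f - mean(f)
  f <- f / max(abs(f))
  1 + amplitude * array(f, dims)
}

#' Generate a synthetic vascular phantom
#'
#' Builds a TOF-MRA-like volume with known ground truth: smooth tubular
#' vessels are rasterized at their stated radii, each aneurysm is an
#' axis-aligned ellipsoidal bulge (axis ratios 0.7-1.3) centered on a vessel
#' surface, and the intensity image is background plus bright foreground,
#' multiplied by a smooth quadratic bias field and corrupted with Rician
#' noise. Fully deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: a list with elements `image`
#'   ([image_volume()]), `vessel_mask` and `aneurysm_mask` ([binary_mask()]),
#'   `aneurysm_centers` (list of `list(center_vox, diameter_mm)`),
#'   `centerlines` (list of mm-coordinate polylines, the ground-truth
#'   centerline oracle) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$volume_shape
  sp <- spec$spacing_mm
  extent <- dims * sp
  diams <- sample_size_mix(spec$n_aneurysms, seed = derive_seed(spec$seed, 7L))
  rng <- spec$aneurysm_diameter_range_mm
  diams <- pmin(pmax(diams, rng[1]), rng[2])
  with_seed(spec$seed, {
    centerlines <- list()
    radii <- numeric(0)
    vessel_mask <- array(FALSE, dims)
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        r <- runif(1, spec$vessel_radius_range_mm[1],
                   spec$vessel_radius_range_mm[2])
        margin <- pmin(r + 2 * sp, extent / 3)
        pts <- vessel_centerline(extent, margin, spec$vessel_style)
        centerlines[[v]] <- pts
        radii[v] <- r
        centers_vox <- sweep(pts, 2, sp, "/") - 0.5  # mm -> 0-based voxel
        rad_vox <- matrix(rep(r / sp, each = nrow(pts)), ncol = 3)
        vessel_mask <- vessel_mask |
          stamp_ellipsoids_cpp(dims, centers_vox, rad_vox)
      }
    }
    aneurysm_mask <- array(FALSE, dims)
    centers <- list()
    if (spec$n_aneurysms > 0) {
      if (spec$n_vessels == 0)
        stop("cannot place aneurysms in a phantom without vessels")
      for (a in seq_len(spec$n_aneurysms)) {
        d <- diams[a]
        placed <- FALSE
        for (try in 1:200) {
          v <- sample.int(length(centerlines), 1)
          pts <- centerlines[[v]]
          p <- pts[sample.int(nrow(pts), 1), ]
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          ctr <- p + radii[v] * u
          s <- runif(3, 0.7, 1.3)
          s <- s / max(s)
          semi <- (d / 2) * s
          if (all(ctr - semi >= 0) && all(ctr + semi <= extent)) {
            ctr_vox <- ctr / sp - 0.5
            aneurysm_mask <- aneurysm_mask |
              stamp_ellipsoids_cpp(dims, matrix(ctr_vox, 1),
                                   matrix(semi / sp, 1))
            centers[[length(centers) + 1]] <-
              list(center_vox = as.integer(round(ctr_vox)) + 1L,
                   diameter_mm = d)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(
            "aneurysm of diameter %.1f mm is too large to fit inside the volume",
            d))
      }
    }
    fg <- vessel_mask | aneurysm_mask
    img <- array(spec$background_intensity, dims)
    img[fg] <- spec$vessel_intensity
    img <- img * random_bias_field(dims, spec$bias_amplitude)
    if (spec$rician_sigma > 0) {
      n <- prod(dims)
      img <- sqrt((img + rnorm(n, 0, spec$rician_sigma))^2 +
                  rnorm(n, 0, spec$rician_sigma)^2)
      dim(img) <- dims
    }
    structure(list(image = image_volume(img, sp),
                   vessel_mask = binary_mask(vessel_mask, sp),
                   aneurysm_mask = binary_mask(aneurysm_mask, sp),
                   aneurysm_centers = centers,
                   centerlines = centerlines,
                   vessel_radii_mm = radii,
                   spec = spec),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case %s: %d vessel voxels, %d aneurysm voxels, %d aneurysm(s)>\n",
    paste(dim(x$image$data), collapse = "x"), sum(x$vessel_mask$data),
    sum(x$aneurysm_mask$data), length(x$aneurysm_centers)))
  invisible(x)
}

#' Write a phantom case to disk
#'
#' Writes image, vessel mask and aneurysm mask as NIfTI files plus a JSON
#' sidecar with aneurysm centers/diameters and the generating spec.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the sidecar path, invisibly.
#' @export
write_phantom_case <- function(case, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$image, file.path(dir, paste0(prefix, "_image.nii.gz")))
  write_volume(case$vessel_mask,
               file.path(dir, paste0(prefix, "_vessels.nii.gz")))
  write_volume(case$aneurysm_mask,
               file.path(dir, paste0(prefix, "_aneurysms.nii.gz")))
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(aneurysm_centers = case$aneurysm_centers,
         spec = unclass(case$spec)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
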