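# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (flood fill, brute-force enumeration, direct formula
# evaluation) and never call the implementation paths they check.

# A quick noise-free phantom with a single aneurysm; small enough for fast
# unit tests.
quick_phantom <- function(seed = 1, noise = 0, bias = 0, shape = c(48, 48, 48),
                          n_aneurysms = 1, style = "spline",
                          radius = c(0.5, 1.2), diam = c(1.8, 6)) {
  generate_phantom(phantom_spec(
    volume_shape = shape, spacing_mm = c(0.3, 0.3, 0.3),
    n_vessels = 2, vessel_radius_range_mm = radius,
    n_aneurysms = n_aneurysms, aneurysm_diameter_range_mm = diam,
    vessel_intensity = 300, background_intensity = 50,
    rician_sigma = noise, bias_amplitude = bias,
    vessel_style = style, seed = seed))
}

# Random blob mask: union of a few random balls, possibly plus a tube.
random_blob_mask <- function(seed, shape = c(24, 24, 24), n_balls = 3,
                             with_tube = FALSE) {
  set.seed(seed)
  m <- array(FALSE, shape)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 6, shape - 6)
    r <- runif(1, 2, 5)
    d2 <- (idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2 + (idx[, 3] - c0[3])^2
    m[d2 <= r^2] <- TRUE
  }
  if (with_tube) {
    y0 <- sample(6:(shape[2] - 6), 1)
    z0 <- sample(6:(shape[3] - 6), 1)
    m[, (y0 - 1):(y0 + 1), (z0 - 1):(z0 + 1)] <- TRUE
  }
  m
}

# Independent 26-connected component counter: plain R flood fill.
count_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  co <- which(mask)
  for (s in co) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p <- arrayInd(i, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        j <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
        if (mask[j] && lab[j] == 0) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  cur
}

# Component sizes via the same naive flood fill.
component_sizes_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  sizes <- integer(0)
  for (s in which(mask)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    n <- 0L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      n <- n + 1L
      p <- arrayInd(i, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        j <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
        if (mask[j] && lab[j] == 0) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
    sizes[cur] <- n
  }
  sizes
}

# Thinness oracle: a thin voxel set contains no fully-foreground 2x2x2 block.
has_thick_block <- function(mask) {
  d <- dim(mask)
  for (z in 1:(d[3] - 1)) for (y in 1:(d[2] - 1)) for (x in 1:(d[1] - 1)) {
    if (all(mask[x:(x + 1), y:(y + 1), z:(z + 1)])) return(TRUE)
  }
  FALSE
}

# Brute-force admissible-origin oracle: every origin whose patch fully
# contains the given component coordinates.
brute_force_origins <- function(comp_coords, patch_size, dims) {
  lo <- apply(comp_coords, 2, min)
  hi <- apply(comp_coords, 2, max)
  ors <- expand.grid(x = seq(hi[1] - patch_size[1] + 1, lo[1]),
                     y = seq(hi[2] - patch_size[2] + 1, lo[2]),
                     z = seq(hi[3] - patch_size[3] + 1, lo[3]))
  as.matrix(ors)
}

# Direct-formula classification metric oracle.
panel_oracle <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = div(tp + tn, tp + fp + tn + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn))
}

# Naive loss oracles: straight summation, no vectorized shortcuts.
dice_oracle <- function(p, g, s = 1) {
  num <- 0; dp <- 0; dg <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * g[i]; dp <- dp + p[i]; dg <- dg + g[i]
  }
  1 - (2 * num + s) / (dp + dg + s)
}
tversky_oracle <- function(p, g, a, b, gam, s = 1) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(p)) {
    tp <- tp + p[i] * g[i]
    fp <- fp + p[i] * (1 - g[i])
    fn <- fn + (1 - p[i]) * g[i]
  }
  # the Tversky index carries half the Dice smoothing (documented choice:
  # alpha = beta = 0.5 then reduces to soft Dice exactly)
  (1 - (tp + s / 2) / (tp + a * fp + b * fn + s / 2))^gam
}
bce_oracle <- function(p, g, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot - (g[i] * log(pi) + (1 - g[i]) * log(1 - pi))
  }
  tot / length(p)
}

# A tiny prepared case (preprocessed phantom + skeleton) reused by sampler
# and pipeline tests.
tiny_prepared_case <- function(seed = 1, case_id = "case", shape = c(48, 48, 48)) {
  ph <- quick_phantom(seed = seed, noise = 10, bias = 0.1, shape = shape)
  cfg <- list(preprocess = preprocess_config(target_spacing_mm = c(0.3, 0.3, 0.3)),
              skeleton = skeleton_config(threshold_strategy = "auto",
                                         min_component_voxels = 200,
                                         closing_radius_vox = 1))
  img <- preprocess_volume(ph$image, cfg$preprocess)
  sk <- vessel_skeleton(img, cfg$skeleton)
  list(case_id = case_id, image = img, aneurysm_mask = ph$aneurysm_mask,
       skeleton = sk$skeleton, vessel_mask = sk$mask, phantom = ph,
       diameter_mm = if (length(ph$aneurysm_centers))
         max(vapply(ph$aneurysm_centers, function(a) a$diameter_mm, 0))
       else NA_real_)
}

# Tiny network spec for fast training tests.
tiny_net <- function(aux = c("bridge", "mid")) {
  network_spec(depth = 1L, base_channels = 2L, block_style = "plain",
               attention = FALSE, aux_tap_levels = aux)
}
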