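# Differentiable layers over the autograd tape. Tensors use the layout
# [X, Y, Z, C, N] (spatial, channel, batch) as column-major R arrays.

op_conv3 <- function(ctx, x, w, b, k = 3L, pad = 1L) {
  xv <- x$val
  val <- conv3d_fw(xv, dim(xv), w$val, b$val, k, pad)$out
  ag_node(ctx, val, bw = function(g) {
    r <- conv3d_bw(xv, dim(xv), g, w$val, k, pad)
    ag_accum(x, r$gx)
    ag_accum(w, r$gw)
    ag_accum(b, r$gb)
  })
}

# Per-channel batch normalization over (spatial, batch); running statistics
# are kept in `state` for inference. Elementwise work runs in C++.
op_bn <- function(ctx, x, gamma, beta, state, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val)
  M <- prod(d[1:3]) * d[5]
  if (training) {
    mo <- chan_moments(x$val, d)
    m <- mo$sum / M
    v <- pmax(mo$sumsq / M - m^2, 0)
    state$rm <- (1 - momentum) * state$rm + momentum * m
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    m <- state$rm
    v <- state$rv
  }
  ivstd <- 1 / sqrt(v + eps)
  xhat <- chan_affine(x$val, d, ivstd, -m * ivstd)
  val <- chan_affine(xhat, d, gamma$val, beta$val)
  ag_node(ctx, val, bw = function(g) {
    ag_accum(gamma, chan_dot(g, xhat, d))
    ag_accum(beta, chan_moments(g, d)$sum)
    if (training) {
      s1 <- gamma$val * chan_moments(g, d)$sum
      s2 <- gamma$val * chan_dot(g, xhat, d)
      gx <- chan_lincomb(g, xhat, d, gamma$val * ivstd, -ivstd * s1 / M,
                         -ivstd * s2 / M)
    } else {
      gx <- chan_affine(g, d, gamma$val * ivstd, numeric(d[4]))
    }
    ag_accum(x, gx)
  })
}

# Parametric rectifier with a learnable per-channel negative slope.
op_prelu <- function(ctx, x, a) {
  d <- dim(x$val)
  xv <- x$val
  val <- prelu_fw(xv, d, a$val)
  ag_node(ctx, val, bw = function(g) {
    r <- prelu_bw(xv, g, d, a$val)
    ag_accum(x, r$gx)
    ag_accum(a, r$ga)
  })
}

op_relu <- function(ctx, x) {
  pos <- x$val > 0
  ag_node(ctx, x$val * pos, bw = function(g) ag_accum(x, g * pos))
}

op_maxpool <- function(ctx, x) {
  d <- dim(x$val)
  r <- maxpool3d_fw(x$val, d)
  ag_node(ctx, r$out, bw = function(g) {
    ag_accum(x, maxpool3d_bw(g, r$idx, d))
  })
}

op_upsample <- function(ctx, x) {
  d <- dim(x$val)
  ag_node(ctx, upsample3d_fw(x$val, d), bw = function(g) {
    ag_accum(x, upsample3d_bw(g, d))
  })
}

op_concat <- function(ctx, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[c(1:3, 5)] == db[c(1:3, 5)]))
  Ca <- da[4]; Cb <- db[4]
  d <- da; d[4] <- Ca + Cb
  val <- array(0, d)
  val[, , , seq_len(Ca), ] <- a$val
  val[, , , Ca + seq_len(Cb), ] <- b$val
  ag_node(ctx, val, bw = function(g) {
    ag_accum(a, g[, , , seq_len(Ca), , drop = FALSE])
    ag_accum(b, g[, , , Ca + seq_len(Cb), , drop = FALSE])
  })
}

op_add <- function(ctx, a, b) {
  ag_node(ctx, a$val + b$val, bw = function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

op_sigmoid <- function(ctx, x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(ctx, s, bw = function(g) ag_accum(x, g * s * (1 - s)))
}

# Global average pooling over the spatial dimensions: [X,Y,Z,C,N] -> [C,N].
op_gap <- function(ctx, x) {
  d <- dim(x$val)
  sp <- prod(d[1:3]); C <- d[4]; N <- d[5]
  val <- matrix(colMeans(matrix(x$val, sp, C * N)), C, N)
  ag_node(ctx, val, bw = function(g) {
    ag_accum(x, array(rep(as.vector(g), each = sp) / sp, d))
  })
}

op_linear <- function(ctx, x, w, b) {
  val <- w$val %*% x$val + b$val
  ag_node(ctx, val, bw = function(g) {
    g <- matrix(g, nrow(w$val))
    ag_accum(x, crossprod(w$val, g))
    ag_accum(w, tcrossprod(g, x$val))
    ag_accum(b, rowSums(g))
  })
}

# Multiply each channel of x by a scalar weight s[C, N] (channel attention).
op_scale_channels <- function(ctx, x, s) {
  d <- dim(x$val)
  sp <- prod(d[1:3])
  scol <- rep(as.vector(s$val), each = sp)
  val <- array(as.vector(x$val) * scol, d)
  ag_node(ctx, val, bw = function(g) {
    gv <- as.vector(g)
    ag_accum(x, array(gv * scol, d))
    C <- d[4]; N <- d[5]
    ag_accum(s, matrix(colSums(matrix(gv * as.vector(x$val), sp, C * N)), C, N))
  })
}

# Multiply every channel of x by a spatial map m of shape [X,Y,Z,1,N]
# (position attention).
op_scale_spatial <- function(ctx, x, m) {
  d <- dim(x$val)
  sp <- prod(d[1:3]); C <- d[4]; N <- d[5]
  mm <- matrix(m$val, sp, N)
  mfull <- mm[, rep(seq_len(N), each = C), drop = FALSE]
  val <- array(as.vector(x$val) * as.vector(mfull), d)
  ag_node(ctx, val, bw = function(g) {
    gv <- matrix(g, sp, C * N)
    ag_accum(x, array(as.vector(gv) * as.vector(mfull), d))
    gx <- gv * matrix(x$val, sp, C * N)
    # sum over channels for each sample
    gm <- sapply(seq_len(N), function(n)
      rowSums(gx[, (n - 1) * C + seq_len(C), drop = FALSE]))
    ag_accum(m, array(gm, dim(m$val)))
  })
}
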