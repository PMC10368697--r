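#' Architecture specification of the multi-task 3D U-Net
#'
#' Encoder-decoder with skip concatenations: each level applies two 3x3x3
#' convolutions (batch-normalized, parametric-rectifier activation)
#' followed by 2x2x2 max pooling; feature channels double at every
#' down-sampling step. The decoder up-samples, halves the channels with an
#' up-convolution, concatenates the skip connection and applies another
#' double-convolution block; a final 1x1x1 convolution maps to the class
#' map. Convolutions use same-padding so a 64^3 patch yields a 64^3
#' probability map. Options: residual basic blocks, a dual (channel +
#' position) attention block at the bridge, and auxiliary classification
#' heads (global average pooling + linear + sigmoid) tapped at the bridge
#' and/or mid-decoder for patch-level supervision.
#'
#' At `depth = 4` with plain blocks, no attention and no auxiliary heads
#' the builder reports 23 convolutional layers (10 encoder + 4
#' up-convolutions + 8 decoder + 1 final), the classic U-Net layer count.
#'
#' @param depth number of down-sampling steps (default 4).
#' @param base_channels channels at the first level (default 16); doubled
#'   per level.
#' @param block_style `"plain"` stacked convolutions or `"residual"` basic
#'   blocks with identity/projection shortcuts.
#' @param attention logical, dual attention at the bridge.
#' @param aux_tap_levels character subset of `c("bridge", "mid")`: where
#'   auxiliary classifier heads are attached; `character(0)` disables
#'   multi-task training.
#' @param in_channels input channels (1 for TOF-MRA).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(depth = 4L, base_channels = 16L,
                         block_style = c("plain", "residual"),
                         attention = FALSE,
                         aux_tap_levels = c("bridge", "mid"),
                         in_channels = 1L) {
  block_style <- match.arg(block_style)
  stopifnot(depth >= 1, base_channels >= 1,
            all(aux_tap_levels %in% c("bridge", "mid")))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 block_style = block_style,
                 attention = isTRUE(attention),
                 aux_tap_levels = aux_tap_levels,
                 in_channels = as.integer(in_channels)),
            class = "network_spec")
}

# ---- parameter constructors ---------------------------------------------

he_conv <- function(cin, cout, k, counter) {
  counter$n <- counter$n + 1L
  list(w = ag_param(matrix(rnorm(k^3 * cin * cout, 0,
                                 sqrt(2 / (k^3 * cin))),
                           k^3 * cin, cout)),
       b = ag_param(numeric(cout)), k = k, pad = if (k == 3) 1L else 0L)
}

new_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(c)
  st$rv <- rep(1, c)
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)), state = st)
}

new_unit <- function(cin, cout, counter, k = 3L) {
  list(conv = he_conv(cin, cout, k, counter), bn = new_bn(cout),
       act = ag_param(rep(0.25, cout)))
}

new_block <- function(cin, cout, style, counter) {
  bl <- list(u1 = new_unit(cin, cout, counter), u2 = new_unit(cout, cout, counter),
             style = style)
  if (style == "residual" && cin != cout) {
    nc <- new.env(parent = emptyenv()); nc$n <- 0L  # projection not counted
    bl$proj <- he_conv(cin, cout, 1L, nc)
  }
  bl
}

new_aux_head <- function(c) {
  list(w = ag_param(matrix(rnorm(c, 0, sqrt(2 / c)), 1, c)),
       b = ag_param(0))
}

new_attention <- function(c) {
  nc <- new.env(parent = emptyenv()); nc$n <- 0L
  r <- max(1L, c %/% 2L)
  list(w1 = ag_param(matrix(rnorm(r * c, 0, sqrt(2 / c)), r, c)),
       b1 = ag_param(numeric(r)),
       w2 = ag_param(matrix(rnorm(c * r, 0, sqrt(2 / r)), c, r)),
       b2 = ag_param(numeric(c)),
       pos = he_conv(c, 1L, 1L, nc))
}

collect_params <- function(x) {
  if (is.environment(x) && isTRUE(x$param)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

collect_bn_states <- function(x) {
  if (is.environment(x) && !is.null(x$rm)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_bn_states)))
  list()
}

#' Build the multi-task 3D U-Net
#'
#' Constructs all parameters (He initialization, deterministic given
#' `seed`) and a forward function. The returned handle reports the number
#' of convolutional layers in the main path.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `unet3d`: a list with `spec`, `params`
#'   (flat list of parameter nodes), `n_conv_layers`, and internals used by
#'   [train_network()] and [predict_volume()].
#' @export
build_model <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  depth <- spec$depth
  ch <- spec$base_channels * 2^(0:depth)
  with_seed(seed, {
    enc <- list()
    cin <- spec$in_channels
    for (li in seq_len(depth + 1)) {
      enc[[li]] <- new_block(cin, ch[li], spec$block_style, counter)
      cin <- ch[li]
    }
    att <- if (spec$attention) new_attention(ch[depth + 1]) else NULL
    ups <- list()
    dec <- list()
    for (li in depth:1) {
      ups[[li]] <- new_unit(ch[li + 1], ch[li], counter)  # up-convolution
      dec[[li]] <- new_block(2 * ch[li], ch[li], spec$block_style, counter)
    }
    fin <- he_conv(ch[1], 1L, 1L, counter)
    # bias the class map toward the sparse foreground prior so early
    # training is not dominated by the background sea
    fin$b$val <- -2

    mid_level <- max(1L, depth %/% 2L)
    aux <- list()
    if ("bridge" %in% spec$aux_tap_levels)
      aux$bridge <- new_aux_head(ch[depth + 1])
    if ("mid" %in% spec$aux_tap_levels)
      aux$mid <- new_aux_head(ch[mid_level])
    net <- list(enc = enc, att = att, ups = ups, dec = dec, fin = fin,
                aux = aux, mid_level = mid_level)
    structure(list(spec = spec, net = net,
                   params = collect_params(net),
                   bn_states = collect_bn_states(net),
                   n_conv_layers = counter$n, seed = as.integer(seed)),
              class = "unet3d")
  })
}

#' @export
print.unet3d <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$val), 0))
  cat(sprintf(
    "<unet3d: depth %d, base %d channels, %s blocks, attention %s, aux [%s]\n  %d conv layers, %d parameters>\n",
    x$spec$depth, x$spec$base_channels, x$spec$block_style,
    if (x$spec$attention) "on" else "off",
    paste(x$spec$aux_tap_levels, collapse = ", "), x$n_conv_layers, np))
  invisible(x)
}

run_unit <- function(ctx, u, h, training) {
  h <- op_conv3(ctx, h, u$conv$w, u$conv$b, u$conv$k, u$conv$pad)
  h <- op_bn(ctx, h, u$bn$gamma, u$bn$beta, u$bn$state, training)
  op_prelu(ctx, h, u$act)
}

run_block <- function(ctx, bl, h, training) {
  h0 <- h
  h <- run_unit(ctx, bl$u1, h, training)
  h1 <- op_conv3(ctx, h, bl$u2$conv$w, bl$u2$conv$b, bl$u2$conv$k,
                 bl$u2$conv$pad)
  h1 <- op_bn(ctx, h1, bl$u2$bn$gamma, bl$u2$bn$beta, bl$u2$bn$state, training)
  if (bl$style == "residual") {
    sc <- if (!is.null(bl$proj))
      op_conv3(ctx, h0, bl$proj$w, bl$proj$b, 1L, 0L) else h0
    h1 <- op_add(ctx, h1, sc)
  }
  op_prelu(ctx, h1, bl$u2$act)
}

run_attention <- function(ctx, at, h) {
  s <- op_gap(ctx, h)
  s <- op_linear(ctx, s, at$w1, at$b1)
  s <- op_relu(ctx, s)
  s <- op_linear(ctx, s, at$w2, at$b2)
  s <- op_sigmoid(ctx, s)
  h <- op_scale_channels(ctx, h, s)
  m <- op_conv3(ctx, h, at$pos$w, at$pos$b, 1L, 0L)
  m <- op_sigmoid(ctx, m)
  op_scale_spatial(ctx, h, m)
}

run_aux_head <- function(ctx, head, h) {
  g <- op_gap(ctx, h)
  op_linear(ctx, g, head$w, head$b)  # logits, 1 x N
}

# Forward pass: x is [X,Y,Z,Cin,N]; returns seg logits node plus a named
# list of auxiliary logit nodes.
forward_unet <- function(model, ctx, x_arr, training = TRUE) {
  spec <- model$spec
  d <- dim(x_arr)
  if (any(d[1:3] %% 2^spec$depth != 0))
    stop(sprintf(
      "input size %s is not divisible by 2^depth = %d; pad to a multiple",
      paste(d[1:3], collapse = "x"), 2^spec$depth))
  net <- model$net
  h <- ag_node(ctx, x_arr)
  skips <- list()
  for (li in seq_len(spec$depth + 1)) {
    h <- run_block(ctx, net$enc[[li]], h, training)
    if (li <= spec$depth) {
      skips[[li]] <- h
      h <- op_maxpool(ctx, h)
    }
  }
  if (!is.null(net$att)) h <- run_attention(ctx, net$att, h)
  aux <- list()
  if (!is.null(net$aux$bridge))
    aux$bridge <- run_aux_head(ctx, net$aux$bridge, h)
  for (li in spec$depth:1) {
    h <- op_upsample(ctx, h)
    h <- run_unit(ctx, net$ups[[li]], h, training)
    h <- op_concat(ctx, skips[[li]], h)
    h <- run_block(ctx, net$dec[[li]], h, training)
    if (li == net$mid_level && !is.null(net$aux$mid))
      aux$mid <- run_aux_head(ctx, net$aux$mid, h)
  }
  seg <- op_conv3(ctx, h, net$fin$w, net$fin$b, 1L, 0L)
  list(seg = seg, aux = aux)
}

#' Run the network on a batch of patches (inference)
#'
#' @param model a [build_model()] handle.
#' @param x array `[X, Y, Z, N]` or `[X, Y, Z]` of standardized intensities.
#' @return list with `seg_probability` (`[X, Y, Z, N]` array in `[0, 1]`)
#'   and `aux_probability` (N-vector, mean over heads; `NULL` when the
#'   model has no auxiliary heads).
#' @export
predict_patches <- function(model, x) {
  d <- dim(x)
  if (length(d) == 3) d <- c(d, 1L)
  xa <- array(x, c(d[1:3], 1L, d[4]))
  ctx <- ag_ctx()
  out <- forward_unet(model, ctx, xa, training = FALSE)
  seg <- 1 / (1 + exp(-out$seg$val))
  aux <- NULL
  if (length(out$aux) > 0) {
    am <- vapply(out$aux, function(a) as.vector(1 / (1 + exp(-a$val))),
                 numeric(d[4]))
    aux <- rowMeans(matrix(am, nrow = d[4]))
  }
  list(seg_probability = array(seg, c(d[1:3], d[4])), aux_probability = aux)
}

#' Save a model checkpoint
#'
#' Serializes the architecture spec, initialization seed and all parameter
#' values (including normalization statistics) so the model can be rebuilt
#' exactly with `load_model()`.
#'
#' @param model a [build_model()] handle.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, seed = model$seed,
               state = model_state(model)), path)
  invisible(path)
}

#' Load a model checkpoint saved by `save_model()`
#'
#' @param path checkpoint path.
#' @return a [build_model()] handle with restored parameters.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = ck$seed)
  model_restore(model, ck$state)
  model
}

#' Deep-copy the parameter values (and normalization statistics) of a model
#' @keywords internal
model_state <- function(model) {
  list(params = lapply(model$params, function(p) p$val),
       bn = lapply(model$bn_states, function(s) list(rm = s$rm, rv = s$rv)))
}

#' Restore parameter values saved by `model_state`
#' @keywords internal
model_restore <- function(model, state) {
  for (i in seq_along(model$params)) model$params[[i]]$val <- state$params[[i]]
  for (i in seq_along(model$bn_states)) {
    model$bn_states[[i]]$rm <- state$bn[[i]]$rm
    model$bn_states[[i]]$rv <- state$bn[[i]]$rv
  }
  invisible(model)
}
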