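# Minimal reverse-mode automatic differentiation on a linear tape. Nodes are
# environments holding a value, an accumulated gradient and a backward
# closure; forward ops append nodes in execution order and backward walks the
# tape in reverse. Dense kernels (convolution, pooling) live in C++.

ag_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$tape <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(ctx, val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  if (!is.null(ctx)) {
    ctx$n <- ctx$n + 1L
    if (ctx$n > length(ctx$tape)) length(ctx$tape) <- 2L * length(ctx$tape)
    ctx$tape[[ctx$n]] <- nd
  }
  nd
}

ag_param <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$param <- TRUE
  nd
}

ag_const <- function(val) ag_param(val)  # no gradient will be requested

ag_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ag_backward <- function(ctx, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(ctx$n))) {
    nd <- ctx$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
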