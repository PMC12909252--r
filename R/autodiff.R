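# Minimal tape-based reverse-mode automatic differentiation over dense R
# arrays. Feature maps are channel-first arrays dim = c(C, D, H, W); scalars
# are length-1 numerics. Every op appends a node to the tape; ag_backward()
# walks the tape in reverse, calling each node's backward closure with its
# accumulated output gradient. The engine is deliberately small: only the ops
# the growth-prediction network needs exist.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# leaf with gradient tracking (parameters, or inputs we differentiate w.r.t.)
ag_leaf <- function(tape, value) ag_node(tape, value)

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ag_value <- function(x) if (is.environment(x)) x$value else x

#' @noRd
ag_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# stop-gradient: value flows, gradient does not
ag_detach <- function(tape, a) ag_node(tape, a$value)

## ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, function(g) { ag_accum(a, g); ag_accum(b, g) })
}

ag_sub <- function(tape, a, b) {
  ag_node(tape, a$value - b$value, function(g) { ag_accum(a, g); ag_accum(b, -g) })
}

ag_mul <- function(tape, a, b) {
  ag_node(tape, a$value * b$value, function(g) {
    ag_accum(a, g * b$value); ag_accum(b, g * a$value)
  })
}

ag_div <- function(tape, a, b) {
  ag_node(tape, a$value / b$value, function(g) {
    ag_accum(a, g / b$value)
    ag_accum(b, -g * a$value / (b$value^2))
  })
}

# scalar constant offset / scale (k is plain numeric, not a node)
ag_adds <- function(tape, a, k) ag_node(tape, a$value + k, function(g) ag_accum(a, g))

ag_scale <- function(tape, a, k) ag_node(tape, a$value * k, function(g) ag_accum(a, g * k))

ag_square <- function(tape, a) {
  ag_node(tape, a$value^2, function(g) ag_accum(a, 2 * g * a$value))
}

ag_abs <- function(tape, a) {
  ag_node(tape, abs(a$value), function(g) ag_accum(a, g * sign(a$value)))
}

## ---- reductions ------------------------------------------------------------

ag_sum <- function(tape, a) {
  ag_node(tape, sum(a$value), function(g) ag_accum(a, array(g, dim(a$value) %||% length(a$value))))
}

ag_mean <- function(tape, a) {
  n <- length(a$value)
  ag_node(tape, sum(a$value) / n,
          function(g) ag_accum(a, array(g / n, dim(a$value) %||% n)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## ---- activations -----------------------------------------------------------

ag_lrelu <- function(tape, a, slope = 0.2) {
  v <- a$value
  out <- ifelse(v > 0, v, slope * v)
  dim(out) <- dim(v)
  ag_node(tape, out, function(g) ag_accum(a, g * ifelse(v > 0, 1, slope)))
}

ag_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(tape, s, function(g) ag_accum(a, g * s * (1 - s)))
}

ag_tanh <- function(tape, a) {
  t <- tanh(a$value)
  ag_node(tape, t, function(g) ag_accum(a, g * (1 - t^2)))
}

## ---- structural ops --------------------------------------------------------

# concatenate two (C, D, H, W) maps along the channel axis
ag_concat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  ca <- da[1]; cb <- db[1]
  out <- array(0, c(ca + cb, da[2:4]))
  ia <- rep(c(rep(TRUE, ca), rep(FALSE, cb)), prod(da[2:4]))
  out[ia] <- a$value
  out[!ia] <- b$value
  ag_node(tape, out, function(g) {
    ag_accum(a, array(g[ia], da))
    ag_accum(b, array(g[!ia], db))
  })
}

## ---- convolution / warp / box sum (Rcpp kernels) ---------------------------

conv_out_dim <- function(d, k, stride, pad) (d + 2L * pad - k) %/% stride + 1L

# w: node holding a (Cin*k^3) x Cout matrix; b: node holding length-Cout
# vector. `input_grad = FALSE` skips the gradient w.r.t. x (first layers,
# whose inputs are data leaves).
ag_conv <- function(tape, x, w, b = NULL, k = 3L, stride = 1L, pad = 1L,
                    input_grad = TRUE) {
  xd <- dim(x$value)
  fast <- k == 3L && stride == 1L && pad == 1L
  y <- if (fast) .conv3d_s1_fwd(x$value, as.integer(xd), w$value)
  else .conv3d_fwd(x$value, as.integer(xd), w$value, k, stride, pad)
  if (!is.null(b)) y <- y + b$value  # recycles over the fastest (channel) axis
  ag_node(tape, y, function(g) {
    bw <- if (fast)
      .conv3d_s1_bwd(x$value, as.integer(xd), w$value, g, input_grad, TRUE)
    else .conv3d_bwd(x$value, as.integer(xd), w$value, g, k, stride, pad,
                     input_grad, TRUE)
    if (input_grad) ag_accum(x, bw$gx)
    ag_accum(w, bw$gw)
    if (!is.null(b)) ag_accum(b, bw$gb)
  })
}

# transposed convolution with k = 2, stride = 2 (exact x2 upsampling).
# Weights are stored as the *adjoint* convolution's matrix: a conv mapping the
# deconv OUTPUT channels to its INPUT channels, so the forward pass is that
# convolution's backward-by-input and vice versa.
ag_deconv <- function(tape, x, w, b = NULL) {
  xd <- dim(x$value)
  cin <- xd[1]
  cout <- nrow(w$value) %/% 8L  # k^3 = 8
  od <- c(cout, xd[2:4] * 2L)
  bw <- .conv3d_bwd(array(0, od), as.integer(od), w$value, x$value,
                    2L, 2L, 0L, TRUE, FALSE)
  y <- bw$gx
  if (!is.null(b)) y <- y + b$value
  ag_node(tape, y, function(g) {
    gx <- .conv3d_fwd(g, as.integer(od), w$value, 2L, 2L, 0L)
    ag_accum(x, gx)
    bww <- .conv3d_bwd(g, as.integer(od), w$value, x$value, 2L, 2L, 0L,
                       FALSE, TRUE)
    ag_accum(w, bww$gw)
    if (!is.null(b)) {
      gb <- rowSums(array(g, c(od[1], prod(od[2:4]))))
      ag_accum(b, gb)
    }
  })
}

# trilinear warp of vol by displacement field u (3, D, H, W), border-clamped
ag_warp <- function(tape, vol, u) {
  vd <- dim(vol$value)
  y <- .warp_fwd(vol$value, as.integer(vd), u$value)
  ag_node(tape, y, function(g) {
    bw <- .warp_bwd(vol$value, as.integer(vd), u$value, g)
    ag_accum(vol, bw$gvol)
    ag_accum(u, bw$gu)
  })
}

# (2r+1)^3 box-window sum, zero padded; self-adjoint
ag_boxsum <- function(tape, x, r) {
  xd <- dim(x$value)
  y <- .boxsum3d(x$value, as.integer(xd), as.integer(r))
  ag_node(tape, y, function(g) {
    ag_accum(x, .boxsum3d(g, as.integer(xd), as.integer(r)))
  })
}

# forward difference of a (C, D, H, W) map along spatial axis (1 = D, 2 = H,
# 3 = W), over the valid positions only (output has one fewer slice)
ag_fdiff <- function(tape, x, axis) {
  v <- x$value
  d <- dim(v)
  n <- d[axis + 1L]
  idx_hi <- switch(axis,
                   v[, 2:n, , , drop = FALSE],
                   v[, , 2:n, , drop = FALSE],
                   v[, , , 2:n, drop = FALSE])
  idx_lo <- switch(axis,
                   v[, 1:(n - 1), , , drop = FALSE],
                   v[, , 1:(n - 1), , drop = FALSE],
                   v[, , , 1:(n - 1), drop = FALSE])
  ag_node(tape, idx_hi - idx_lo, function(g) {
    gx <- array(0, d)
    if (axis == 1L) {
      gx[, 2:n, , ] <- gx[, 2:n, , ] + g
      gx[, 1:(n - 1), , ] <- gx[, 1:(n - 1), , ] - g
    } else if (axis == 2L) {
      gx[, , 2:n, ] <- gx[, , 2:n, ] + g
      gx[, , 1:(n - 1), ] <- gx[, , 1:(n - 1), ] - g
    } else {
      gx[, , , 2:n] <- gx[, , , 2:n] + g
      gx[, , , 1:(n - 1)] <- gx[, , , 1:(n - 1)] - g
    }
    ag_accum(x, gx)
  })
}
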