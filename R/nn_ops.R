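# Differentiable tensor operations on (C, H, W, N) arrays.

dims4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a (C, H, W, N) array")
  d
}

# ---- convolution ---------------------------------------------------------

# w: (Cin*KH*KW) x Cout matrix; b: length-Cout vector or NULL.
op_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && stride == 1L) return(op_conv1x1(x, w, b))
  xv <- ag_value(x); wv <- ag_value(w)
  d <- dims4(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Cout <- ncol(wv)
  cols <- im2col_cpp(xv, C, H, W, N, k, k, stride, pad, pad) # positions x C*k*k
  y <- t(cols %*% wv)
  if (!is.null(b)) y <- y + ag_value(b)
  HO <- (H + 2 * pad - k) %/% stride + 1L
  WO <- (W + 2 * pad - k) %/% stride + 1L
  dim(y) <- c(Cout, HO, WO, N)
  ag_node(y, backward = function(node) {
    g <- node$grad
    dim(g) <- c(Cout, HO * WO * N)
    gm <- t(g)
    if (!is.null(b) && is_ag(b)) ag_accum(b, .rowSums(g, Cout, ncol(g)))
    if (is_ag(w) && (w$is_param || !is.null(w$backward))) {
      ag_accum(w, crossprod(cols, gm))
    }
    if (is_ag(x) && (x$is_param || !is.null(x$backward))) {
      dx <- col2im_cpp(tcrossprod(gm, ag_value(w)), C, H, W, N, k, k, stride, pad, pad)
      ag_accum(x, dx)
    }
  })
}

# Pointwise convolution: a plain gemm on the (C, H*W*N) matrix view.
op_conv1x1 <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  d <- dims4(xv)
  C <- d[1]
  M <- d[2] * d[3] * d[4]
  xm <- xv
  dim(xm) <- c(C, M)
  y <- crossprod(wv, xm)
  if (!is.null(b)) y <- y + ag_value(b)
  dim(y) <- c(ncol(wv), d[2], d[3], d[4])
  ag_node(y, backward = function(node) {
    g <- node$grad
    dim(g) <- c(ncol(wv), M)
    if (!is.null(b) && is_ag(b)) ag_accum(b, .rowSums(g, ncol(wv), M))
    if (is_ag(w) && (w$is_param || !is.null(w$backward))) {
      ag_accum(w, tcrossprod(xm, g))
    }
    if (is_ag(x) && (x$is_param || !is.null(x$backward))) {
      dx <- ag_value(w) %*% g
      dim(dx) <- d
      ag_accum(x, dx)
    }
  })
}

# ---- batch normalization -------------------------------------------------

# state: environment with running_mean, running_var; updated when training.
# relu = TRUE fuses the following ReLU into the same node.
op_bn <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5,
                  relu = FALSE) {
  xv <- ag_value(x)
  d <- dims4(xv)
  C <- d[1]; m <- prod(d[2:4])
  xm <- xv
  dim(xm) <- c(C, m)
  training <- .ag$training
  if (training) {
    mu <- .rowMeans(xm, C, m)
    va <- .rowMeans((xm - mu)^2, C, m)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  isd <- 1 / sqrt(va + eps)
  xhat <- (xv - mu) * isd                    # recycling over fastest dim C
  y <- xhat * ag_value(gamma) + ag_value(beta)
  mask <- NULL
  if (relu) {
    mask <- y > 0
    y <- y * mask
  }
  ag_node(y, backward = function(node) {
    g <- node$grad
    if (relu) g <- g * mask
    gm <- g
    dim(gm) <- c(C, m)
    xh <- xhat
    dim(xh) <- c(C, m)
    ag_accum(gamma, .rowSums(gm * xh, C, m))
    ag_accum(beta, .rowSums(gm, C, m))
    if (!(is_ag(x) && (x$is_param || !is.null(x$backward)))) return(invisible(NULL))
    gv <- ag_value(gamma)
    if (training) {
      dxhat <- gm * gv
      dx <- (dxhat - .rowMeans(dxhat, C, m) - xh * .rowMeans(dxhat * xh, C, m)) * isd
      dim(dx) <- d
      ag_accum(x, dx)
    } else {
      dx <- g * (gv * isd)
      ag_accum(x, dx)
    }
  })
}

# ---- pointwise and structural ops ---------------------------------------

op_relu <- function(x) {
  xv <- ag_value(x)
  mask <- xv > 0
  ag_node(xv * mask, backward = function(node) ag_accum(x, node$grad * mask))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-ag_value(x)))
  ag_node(y, backward = function(node) ag_accum(x, node$grad * y * (1 - y)))
}

op_add <- function(x, y) {
  ag_node(ag_value(x) + ag_value(y), backward = function(node) {
    ag_accum(x, node$grad)
    ag_accum(y, node$grad)
  })
}

op_scale <- function(x, a) {
  ag_node(ag_value(x) * a, backward = function(node) ag_accum(x, node$grad * a))
}

# Multiply by a per-(channel, sample) gate, gate dim = (C, N).
op_mul_channel_gate <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dims4(xv)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  full <- gv[, rep(seq_len(N), each = HW), drop = FALSE]
  dim(full) <- d
  ag_node(xv * full, backward = function(node) {
    g <- node$grad
    ag_accum(x, g * full)
    gx <- g * xv
    dim(gx) <- c(C, HW, N)
    dg <- matrix(0, C, N)
    for (n in seq_len(N)) dg[, n] <- rowSums(gx[, , n, drop = FALSE])
    ag_accum(gate, dg)
  })
}

# Multiply by a per-pixel gate, gate dim = (1, H, W, N), broadcast over C.
op_mul_spatial_gate <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dims4(xv)
  C <- d[1]
  full <- array(rep(as.vector(gv), each = C), d)
  ag_node(xv * full, backward = function(node) {
    g <- node$grad
    ag_accum(x, g * full)
    dg <- colSums(matrix(g * xv, C))
    dim(dg) <- c(1L, d[2], d[3], d[4])
    ag_accum(gate, dg)
  })
}

op_concat_ch <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dims4(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  out <- array(0, c(sum(Cs), d1[2], d1[3], d1[4]))
  off <- 0L
  for (i in seq_along(vals)) {
    out[off + seq_len(Cs[i]), , , ] <- vals[[i]]
    off <- off + Cs[i]
  }
  ag_node(out, backward = function(node) {
    g <- node$grad
    off <- 0L
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], g[off + seq_len(Cs[i]), , , , drop = FALSE])
      off <- off + Cs[i]
    }
  })
}

op_maxpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dims4(xv)
  r <- maxpool2_cpp(xv, d[1], d[2], d[3], d[4])
  arg <- r$argmax
  ag_node(r$value, backward = function(node) {
    dx <- numeric(length(xv))
    dx[arg] <- node$grad              # pooling windows are disjoint
    dim(dx) <- d
    ag_accum(x, dx)
  })
}

op_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dims4(xv)
  ih <- rep(seq_len(d[2]), each = 2L)
  iw <- rep(seq_len(d[3]), each = 2L)
  y <- xv[, ih, iw, , drop = FALSE]
  ag_node(y, backward = function(node) {
    g <- node$grad
    oh <- seq.int(1L, 2L * d[2], 2L)
    ow <- seq.int(1L, 2L * d[3], 2L)
    dx <- g[, oh, ow, , drop = FALSE] + g[, oh + 1L, ow, , drop = FALSE] +
      g[, oh, ow + 1L, , drop = FALSE] + g[, oh + 1L, ow + 1L, , drop = FALSE]
    ag_accum(x, dx)
  })
}

# Global average / max pooling -> (C, N).
op_gap <- function(x) {
  xv <- ag_value(x)
  d <- dims4(xv)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- xv
  dim(xm) <- c(C, HW, N)
  y <- matrix(0, C, N)
  for (n in seq_len(N)) y[, n] <- rowMeans(xm[, , n, drop = FALSE])
  ag_node(y, backward = function(node) {
    g <- node$grad / HW
    full <- g[, rep(seq_len(N), each = HW), drop = FALSE]
    dim(full) <- d
    ag_accum(x, full)
  })
}

op_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dims4(xv)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- xv
  dim(xm) <- c(C, HW, N)
  y <- matrix(0, C, N)
  idx <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    for (cc in seq_len(C)) {
      j <- which.max(xm[cc, , n])
      idx[cc, n] <- j
      y[cc, n] <- xm[cc, j, n]
    }
  }
  ag_node(y, backward = function(node) {
    g <- node$grad
    dx <- array(0, d)
    dim(dx) <- c(C, HW, N)
    for (n in seq_len(N)) {
      for (cc in seq_len(C)) dx[cc, idx[cc, n], n] <- g[cc, n]
    }
    dim(dx) <- d
    ag_accum(x, dx)
  })
}

# Fully connected on (In, N) matrices: y = w %*% x + b.
op_linear <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  y <- wv %*% xv
  if (!is.null(b)) y <- y + ag_value(b)
  ag_node(y, backward = function(node) {
    g <- node$grad
    if (!is.null(b)) ag_accum(b, rowSums(g))
    ag_accum(w, g %*% t(ag_value(x)))
    ag_accum(x, crossprod(ag_value(w), g))
  })
}

# Center crop dims 2 and 3 to (out_h, out_w).
op_crop <- function(x, out_h, out_w) {
  xv <- ag_value(x)
  d <- dims4(xv)
  if (out_h > d[2] || out_w > d[3]) {
    stop("crop size exceeds input (", d[2], "x", d[3], " -> ", out_h, "x", out_w, ")")
  }
  oh <- (d[2] - out_h) %/% 2L
  ow <- (d[3] - out_w) %/% 2L
  ih <- oh + seq_len(out_h)
  iw <- ow + seq_len(out_w)
  y <- xv[, ih, iw, , drop = FALSE]
  ag_node(y, backward = function(node) {
    dx <- array(0, d)
    dx[, ih, iw, ] <- node$grad
    ag_accum(x, dx)
  })
}

# Channel-wise softmax over dim 1.
op_softmax_ch <- function(x) {
  xv <- ag_value(x)
  d <- dims4(xv)
  C <- d[1]
  xm <- matrix(xv, C)
  mx <- do.call(pmax, c(asplit(xm, 1), list(na.rm = FALSE)))
  e <- exp(xm - rep(mx, each = C))
  p <- e / rep(colSums(e), each = C)
  pv <- p
  dim(pv) <- d
  ag_node(pv, backward = function(node) {
    g <- matrix(node$grad, C)
    dot <- colSums(p * g)
    dz <- p * (g - rep(dot, each = C))
    dim(dz) <- d
    ag_accum(x, dz)
  })
}

# ---- finite-difference gradient maps (shared with losses) ---------------

# Central differences along width (horizontal) with one-sided borders.
fd_h <- function(x) {
  d <- dim(x)
  W <- d[3]
  y <- array(0, d)
  if (W >= 3) {
    y[, , 2:(W - 1), ] <- (x[, , 3:W, , drop = FALSE] - x[, , 1:(W - 2), , drop = FALSE]) / 2
  }
  y[, , 1, ] <- x[, , 2, , drop = FALSE] - x[, , 1, , drop = FALSE]
  y[, , W, ] <- x[, , W, , drop = FALSE] - x[, , W - 1, , drop = FALSE]
  y
}

fd_v <- function(x) {
  d <- dim(x)
  H <- d[2]
  y <- array(0, d)
  if (H >= 3) {
    y[, 2:(H - 1), , ] <- (x[, 3:H, , , drop = FALSE] - x[, 1:(H - 2), , , drop = FALSE]) / 2
  }
  y[, 1, , ] <- x[, 2, , , drop = FALSE] - x[, 1, , , drop = FALSE]
  y[, H, , ] <- x[, H, , , drop = FALSE] - x[, H - 1, , , drop = FALSE]
  y
}

# Adjoints of fd_h / fd_v (verified against the explicit operator matrix).
fd_h_adj <- function(g) {
  d <- dim(g)
  W <- d[3]
  z <- array(0, d)
  if (W >= 3) {
    z[, , 1:(W - 2), ] <- z[, , 1:(W - 2), , drop = FALSE] - g[, , 2:(W - 1), , drop = FALSE] / 2
    z[, , 3:W, ] <- z[, , 3:W, , drop = FALSE] + g[, , 2:(W - 1), , drop = FALSE] / 2
  }
  z[, , 1, ] <- z[, , 1, , drop = FALSE] - g[, , 1, , drop = FALSE]
  z[, , 2, ] <- z[, , 2, , drop = FALSE] + g[, , 1, , drop = FALSE]
  z[, , W - 1, ] <- z[, , W - 1, , drop = FALSE] - g[, , W, , drop = FALSE]
  z[, , W, ] <- z[, , W, , drop = FALSE] + g[, , W, , drop = FALSE]
  z
}

fd_v_adj <- function(g) {
  d <- dim(g)
  H <- d[2]
  z <- array(0, d)
  if (H >= 3) {
    z[, 1:(H - 2), , ] <- z[, 1:(H - 2), , , drop = FALSE] - g[, 2:(H - 1), , , drop = FALSE] / 2
    z[, 3:H, , ] <- z[, 3:H, , , drop = FALSE] + g[, 2:(H - 1), , , drop = FALSE] / 2
  }
  z[, 1, , ] <- z[, 1, , , drop = FALSE] - g[, 1, , , drop = FALSE]
  z[, 2, , ] <- z[, 2, , , drop = FALSE] + g[, 1, , , drop = FALSE]
  z[, H - 1, , ] <- z[, H - 1, , , drop = FALSE] - g[, H, , , drop = FALSE]
  z[, H, , ] <- z[, H, , , drop = FALSE] + g[, H, , , drop = FALSE]
  z
}
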