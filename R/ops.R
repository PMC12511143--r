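# Differentiable array operations.  Feature maps are numeric arrays with
# dim c(H, W, N, C): height, width, batch, channels.  Channels occupy the
# slowest axis so channel concatenation and splitting are contiguous.

fm_dims <- function(x) {
  d <- dim(tn_value(x))
  stopifnot(length(d) == 4L)
  d
}

#' @keywords internal
fm_new <- function(H, W, N, C, data = 0) array(data, dim = c(H, W, N, C))

# ---- dense convolution via im2col + GEMM -----------------------------------

op_conv2d <- function(x, w, stride = 1L, pad = NULL) {
  d <- fm_dims(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  wd <- dim(tn_value(w))
  k <- wd[1]; Cin <- wd[3]; Cout <- wd[4]
  stopifnot(wd[2] == k, Cin == C)
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  wm <- tn_value(w); dim(wm) <- c(k * k * Cin, Cout)
  one_by_one <- (k == 1L && stride == 1L && pad == 0L)
  col <- NULL
  if (one_by_one) {
    xm <- tn_value(x); dim(xm) <- c(H * W * N, C)
    y <- xm %*% wm
  } else {
    col <- im2col_cpp(tn_value(x), H, W, N, C, k, stride, pad)
    y <- col %*% wm
  }
  dim(y) <- c(Ho, Wo, N, Cout)
  mac_add(as.double(Ho) * Wo * N * k * k * Cin * Cout)
  xn <- as_tn(x); wn <- as_tn(w)
  if (!.giwt$grad_enabled) return(tn_leaf(y))
  tn_op(y, list(xn, wn), function(g) {
    gm <- g; dim(gm) <- c(Ho * Wo * N, Cout)
    if (one_by_one) {
      xm2 <- xn$v; dim(xm2) <- c(H * W * N, C)
      dW <- crossprod(xm2, gm)
      dx <- gm %*% t(wm)
      dim(dx) <- c(H, W, N, C)
    } else {
      dW <- crossprod(col, gm)
      dcol <- gm %*% t(wm)
      dx <- col2im_cpp(dcol, H, W, N, C, k, stride, pad)
      dim(dx) <- c(H, W, N, C)
    }
    dim(dW) <- c(k, k, Cin, Cout)
    list(dx, dW)
  })
}

# ---- depthwise convolution --------------------------------------------------

op_dwconv2d <- function(x, w, stride = 1L, pad = NULL) {
  d <- fm_dims(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  wd <- dim(tn_value(w))
  k <- wd[1]
  stopifnot(wd[2] == k, wd[3] == C)
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  y <- dwconv_fwd2_cpp(tn_value(x), tn_value(w), H, W, N, C, k, stride, pad)
  dim(y) <- c(Ho, Wo, N, C)
  mac_add(as.double(Ho) * Wo * N * k * k * C)
  xn <- as_tn(x); wn <- as_tn(w)
  tn_op(y, list(xn, wn), function(g) {
    r <- dwconv_bwd2_cpp(g, xn$v, wn$v, H, W, N, C, k, stride, pad)
    dx <- r$dx; dim(dx) <- c(H, W, N, C)
    dw <- r$dw; dim(dw) <- c(k, k, C)
    list(dx, dw)
  })
}

# ---- batch normalization ----------------------------------------------------

# state: environment with running_mean, running_var (plain vectors).
op_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- fm_dims(x)
  M <- d[1] * d[2] * d[3]; C <- d[4]
  xv <- tn_value(x)
  gv <- tn_value(gamma); bv <- tn_value(beta)
  if (training) {
    st <- ch_stats_cpp(xv, M, C)
    mu <- st$sum / M
    va <- st$sumsq / M - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    unb <- if (M > 1) va * M / (M - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(pmax(va, 0) + eps)
  a <- gv * inv_sd
  y <- ch_affine_cpp(xv, a, bv - a * mu, M, C)
  dim(y) <- d
  xn <- as_tn(x); gn <- as_tn(gamma); bn <- as_tn(beta)
  tn_op(y, list(xn, gn, bn), function(g) {
    r <- bn_bwd_cpp(g, xn$v, mu, inv_sd, gv, M, C, training)
    dx <- r$dx
    dim(dx) <- d
    list(dx, r$dgamma, r$dbeta)
  })
}

# ---- activations ------------------------------------------------------------

op_silu <- function(x) {
  xv <- tn_value(x)
  y <- silu_fwd_cpp(xv)
  attributes(y) <- attributes(xv)
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- silu_bwd_cpp(g, xn$v)
    attributes(dx) <- attributes(xn$v)
    list(dx)
  })
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-tn_value(x)))
  xn <- as_tn(x)
  tn_op(s, list(xn), function(g) list(g * s * (1 - s)))
}

# ---- structural ops ---------------------------------------------------------

op_add <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  tn_op(an$v + bn$v, list(an, bn), function(g) list(g, g))
}

# Per-channel scaling: s has length C.
op_scale_channels <- function(x, s) {
  d <- fm_dims(x)
  M <- d[1] * d[2] * d[3]
  sv <- tn_value(s)
  y <- ch_mul_cpp(tn_value(x), sv, M, d[4])
  dim(y) <- d
  xn <- as_tn(x); sn <- as_tn(s)
  tn_op(y, list(xn, sn), function(g) {
    r <- ch_mul_bwd_cpp(g, xn$v, sv, M, d[4])
    dx <- r$dx
    dim(dx) <- d
    list(dx, r$ds)
  })
}

op_concat_c <- function(xs) {
  nodes <- lapply(xs, as_tn)
  ds <- lapply(nodes, fm_dims)
  d0 <- ds[[1]]
  cs <- vapply(ds, function(d) d[4], numeric(1))
  y <- unlist(lapply(nodes, function(n) as.vector(n$v)), use.names = FALSE)
  dim(y) <- c(d0[1], d0[2], d0[3], sum(cs))
  block <- d0[1] * d0[2] * d0[3]
  tn_op(y, nodes, function(g) {
    out <- vector("list", length(nodes))
    off <- 0
    for (i in seq_along(nodes)) {
      len <- block * cs[i]
      gi <- g[(off + 1):(off + len)]
      dim(gi) <- c(d0[1], d0[2], d0[3], cs[i])
      out[[i]] <- gi
      off <- off + len
    }
    out
  })
}

# Channel slice [from, to] (1-based, inclusive).
op_slice_c <- function(x, from, to) {
  d <- fm_dims(x)
  block <- d[1] * d[2] * d[3]
  idx <- (block * (from - 1) + 1):(block * to)
  y <- tn_value(x)[idx]
  dim(y) <- c(d[1], d[2], d[3], to - from + 1L)
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- array(0, dim = d)
    dx[idx] <- g
    list(dx)
  })
}

op_maxpool <- function(x, k, stride = 1L, pad = NULL) {
  d <- fm_dims(x)
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  r <- maxpool_fwd_cpp(tn_value(x), d[1], d[2], d[3], d[4], k, stride, pad)
  y <- r$y
  dim(y) <- c(Ho, Wo, d[3], d[4])
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- maxpool_bwd_cpp(g, r$idx, prod(d))
    dim(dx) <- d
    list(dx)
  })
}

op_upsample2 <- function(x) {
  d <- fm_dims(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  y <- tn_value(x)[ri, ci, , , drop = FALSE]
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    odd_r <- seq(1L, 2L * d[1], by = 2L)
    odd_c <- seq(1L, 2L * d[2], by = 2L)
    dx <- g[odd_r, odd_c, , , drop = FALSE] + g[odd_r + 1L, odd_c, , , drop = FALSE] +
      g[odd_r, odd_c + 1L, , , drop = FALSE] + g[odd_r + 1L, odd_c + 1L, , , drop = FALSE]
    list(dx)
  })
}

# Global average pool -> (N, C) matrix.
op_gap <- function(x) {
  d <- fm_dims(x)
  hw <- d[1] * d[2]
  xm <- tn_value(x); dim(xm) <- c(hw, d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- array(rep(as.vector(g) / hw, each = hw), dim = d)
    list(dx)
  })
}

# Dense layer on (N, Cin) matrices; w (Cin, Cout), b length Cout.
op_dense <- function(x, w, b = NULL) {
  xn <- as_tn(x); wn <- as_tn(w)
  xm <- xn$v; wm <- wn$v
  y <- xm %*% wm
  mac_add(as.double(nrow(xm)) * ncol(xm) * ncol(wm))
  if (!is.null(b)) {
    bn <- as_tn(b)
    y <- y + rep(bn$v, each = nrow(xm))
    tn_op(y, list(xn, wn, bn), function(g) {
      list(g %*% t(wm), crossprod(xm, g), colSums(g))
    })
  } else {
    tn_op(y, list(xn, wn), function(g) list(g %*% t(wm), crossprod(xm, g)))
  }
}

# Broadcast-multiply a feature map by per-image-per-channel gates s (N, C).
op_gate_channels <- function(x, s) {
  d <- fm_dims(x)
  hw <- d[1] * d[2]
  sn <- as_tn(s); xn <- as_tn(x)
  sx <- rep(as.vector(sn$v), each = hw)
  y <- tn_value(x) * sx
  dim(y) <- d
  tn_op(y, list(xn, sn), function(g) {
    dx <- g * sx
    dim(dx) <- d
    prod_m <- g * as.vector(xn$v)
    dim(prod_m) <- c(hw, d[3] * d[4])
    ds <- matrix(colSums(prod_m), d[3], d[4])
    list(dx, ds)
  })
}

# ---- generic matrix / elementwise ops --------------------------------------

# Token-space attention products; not counted as MACs (the FLOP convention
# covers convolutions and fully-connected layers only).
op_matmul <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  y <- an$v %*% bn$v
  tn_op(y, list(an, bn), function(g) list(g %*% t(bn$v), crossprod(an$v, g)))
}

op_transpose <- function(a) {
  an <- as_tn(a)
  tn_op(t(an$v), list(an), function(g) list(t(g)))
}

op_softmax_rows <- function(x) {
  xn <- as_tn(x)
  xv <- xn$v
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  p <- e / rowSums(e)
  tn_op(p, list(xn), function(g) list(p * (g - rowSums(g * p))))
}

op_mul <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  tn_op(an$v * bn$v, list(an, bn), function(g) list(g * bn$v, g * an$v))
}

op_sub <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  tn_op(an$v - bn$v, list(an, bn), function(g) list(g, -g))
}

op_div <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  y <- an$v / bn$v
  tn_op(y, list(an, bn), function(g) list(g / bn$v, -g * y / bn$v))
}

op_scalar_mul <- function(x, s) {
  xn <- as_tn(x)
  tn_op(xn$v * s, list(xn), function(g) list(g * s))
}

op_scalar_add <- function(x, s) {
  xn <- as_tn(x)
  tn_op(xn$v + s, list(xn), function(g) list(g))
}

op_square <- function(x) {
  xn <- as_tn(x)
  tn_op(xn$v^2, list(xn), function(g) list(2 * g * xn$v))
}

op_sqrt <- function(x) {
  xn <- as_tn(x)
  y <- sqrt(xn$v)
  tn_op(y, list(xn), function(g) list(g * 0.5 / pmax(y, 1e-12)))
}

op_atan <- function(x) {
  xn <- as_tn(x)
  tn_op(atan(xn$v), list(xn), function(g) list(g / (1 + xn$v^2)))
}

op_pmax2 <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  mask <- an$v >= bn$v
  tn_op(pmax(an$v, bn$v), list(an, bn),
        function(g) list(g * mask, g * (!mask)))
}

op_pmin2 <- function(a, b) {
  an <- as_tn(a); bn <- as_tn(b)
  mask <- an$v <= bn$v
  tn_op(pmin(an$v, bn$v), list(an, bn),
        function(g) list(g * mask, g * (!mask)))
}

op_clamp_min <- function(x, lo) {
  xn <- as_tn(x)
  mask <- xn$v > lo
  tn_op(pmax(xn$v, lo), list(xn), function(g) list(g * mask))
}

op_sum <- function(x) {
  xn <- as_tn(x)
  d <- dim(xn$v)
  tn_op(sum(xn$v), list(xn), function(g) {
    dx <- array(g, dim = if (is.null(d)) length(xn$v) else d)
    list(dx)
  })
}

# Weighted sum with constant weights (same shape as x).
op_dot_const <- function(x, w) {
  xn <- as_tn(x)
  d <- dim(xn$v)
  tn_op(sum(xn$v * w), list(xn), function(g) {
    dx <- g * w
    if (!is.null(d)) dim(dx) <- d
    list(dx)
  })
}

op_mean <- function(x) op_scalar_mul(op_sum(x), 1 / length(tn_value(x)))

# Select matrix rows (1-based indices); backward scatter-adds.
op_gather_rows <- function(x, idx) {
  xn <- as_tn(x)
  y <- xn$v[idx, , drop = FALSE]
  tn_op(y, list(xn), function(g) {
    dx <- matrix(0, nrow(xn$v), ncol(xn$v))
    for (i in seq_along(idx)) dx[idx[i], ] <- dx[idx[i], ] + g[i, ]
    list(dx)
  })
}

op_reshape <- function(x, newdim) {
  xn <- as_tn(x)
  d <- dim(xn$v)
  y <- xn$v
  dim(y) <- newdim
  tn_op(y, list(xn), function(g) {
    dim(g) <- d
    list(g)
  })
}

op_col <- function(x, j) {
  xn <- as_tn(x)
  d <- dim(xn$v)
  tn_op(xn$v[, j], list(xn), function(g) {
    dx <- matrix(0, d[1], d[2])
    dx[, j] <- g
    list(dx)
  })
}

op_cols <- function(x, from, to) {
  xn <- as_tn(x)
  d <- dim(xn$v)
  tn_op(xn$v[, from:to, drop = FALSE], list(xn), function(g) {
    dx <- matrix(0, d[1], d[2])
    dx[, from:to] <- g
    list(dx)
  })
}

op_detach <- function(x) tn_leaf(tn_value(x))

op_bias_channels <- function(x, b) {
  d <- fm_dims(x)
  M <- d[1] * d[2] * d[3]
  xn <- as_tn(x); bn <- as_tn(b)
  y <- tn_value(x) + rep(bn$v, each = M)
  dim(y) <- d
  tn_op(y, list(xn, bn), function(g) {
    gm <- g; dim(gm) <- c(M, d[4])
    list(g, colSums(gm))
  })
}

# Edge-replication padding at the bottom/right (for odd sizes ahead of a DWT).
op_pad_edge <- function(x, bottom = 0L, right = 0L) {
  d <- fm_dims(x)
  ri <- c(seq_len(d[1]), rep(d[1], bottom))
  ci <- c(seq_len(d[2]), rep(d[2], right))
  y <- tn_value(x)[ri, ci, , , drop = FALSE]
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
    if (bottom > 0) dx[d[1], , , ] <- dx[d[1], , , ] + g[d[1] + 1L, seq_len(d[2]), , ]
    if (right > 0) dx[, d[2], , ] <- dx[, d[2], , ] + g[seq_len(d[1]), d[2] + 1L, , ]
    if (bottom > 0 && right > 0) dx[d[1], d[2], , ] <- dx[d[1], d[2], , ] + g[d[1] + 1L, d[2] + 1L, , ]
    list(dx)
  })
}

op_crop <- function(x, h, w) {
  d <- fm_dims(x)
  if (d[1] == h && d[2] == w) return(as_tn(x))
  y <- tn_value(x)[seq_len(h), seq_len(w), , , drop = FALSE]
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- array(0, dim = d)
    dx[seq_len(h), seq_len(w), , ] <- g
    list(dx)
  })
}

# Extract image n of a feature map as a (H*W, C) token matrix, and its inverse.
op_image_mat <- function(x, n) {
  d <- fm_dims(x)
  y <- tn_value(x)[, , n, , drop = FALSE]
  dim(y) <- c(d[1] * d[2], d[4])
  xn <- as_tn(x)
  tn_op(y, list(xn), function(g) {
    dx <- array(0, dim = d)
    dim(g) <- c(d[1], d[2], 1, d[4])
    dx[, , n, ] <- g
    list(dx)
  })
}

op_stack_images <- function(mats, H, W, C) {
  nodes <- lapply(mats, as_tn)
  N <- length(nodes)
  y <- array(0, dim = c(H, W, N, C))
  for (n in seq_len(N)) {
    m <- nodes[[n]]$v
    dim(m) <- c(H, W, 1, C)
    y[, , n, ] <- m
  }
  tn_op(y, nodes, function(g) {
    lapply(seq_len(N), function(n) {
      gi <- g[, , n, , drop = FALSE]
      dim(gi) <- c(H * W, C)
      gi
    })
  })
}

# ---- loss primitives --------------------------------------------------------

# Sum of elementwise binary cross-entropy with logits, weighted by constant w.
op_bce_sum <- function(logits, target, w = 1) {
  xn <- as_tn(logits)
  xv <- xn$v
  l <- pmax(xv, 0) - xv * target + log1p(exp(-abs(xv)))
  v <- sum(w * l)
  tn_op(v, list(xn), function(g) {
    s <- 1 / (1 + exp(-xv))
    dx <- g * w * (s - target)
    if (!is.null(dim(xv))) dim(dx) <- dim(xv)
    list(dx)
  })
}

# Distribution-focal cross-entropy: logits (M, K) rows are softmax bins, t in
# [0, K-1] continuous; the two adjacent integer bins are weighted linearly.
# Returns the per-row-weighted sum; wrow are constant row weights.
op_dfl_sum <- function(logits, t, wrow = 1) {
  xn <- as_tn(logits)
  xv <- xn$v
  K <- ncol(xv)
  tl <- floor(t)
  tr <- pmin(tl + 1, K - 1)
  wl <- tr - t
  wr <- 1 - wl
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  p <- e / rowSums(e)
  logp <- (xv - m) - log(rowSums(e))
  M <- nrow(xv)
  pick <- function(cols) logp[cbind(seq_len(M), cols + 1L)]
  v <- sum(wrow * (-(wl * pick(tl) + wr * pick(tr))))
  tn_op(v, list(xn), function(g) {
    tgt <- matrix(0, M, K)
    tgt[cbind(seq_len(M), tl + 1L)] <- tgt[cbind(seq_len(M), tl + 1L)] + wl
    tgt[cbind(seq_len(M), tr + 1L)] <- tgt[cbind(seq_len(M), tr + 1L)] + wr
    list(g * wrow * (p - tgt))
  })
}
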