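# Building blocks inherited from the YOLOv11-small baseline conventions
# (width multiplier 0.5, depth multiplier 0.5) plus the wavelet variants
# Bottleneck_WT / C3K_WT / C3K2_WT and squeeze-and-excitation attention.

#' Squeeze-and-excitation configuration
#' @param channels channel count.
#' @param reduction bottleneck reduction ratio `r` (default 16).
#' @return object of class `se_config`.
#' @export
se_config <- function(channels, reduction = 16L) {
  channels <- as.integer(channels); reduction <- as.integer(reduction)
  if (channels %/% reduction < 1L) stop("channels / reduction must be >= 1", call. = FALSE)
  structure(list(channels = channels, reduction = reduction), class = "se_config")
}

nn_se <- function(cfg) {
  self <- new_layer("se")
  c <- cfg$channels
  h <- max(1L, c %/% cfg$reduction)
  self$cfg <- cfg
  self$params$w1 <- tn_param(init_kaiming(c(c, h), fan_in = c))
  self$params$b1 <- tn_param(rep(0, h))
  self$params$w2 <- tn_param(init_kaiming(c(h, c), fan_in = h))
  self$params$b2 <- tn_param(rep(0, c))
  self$forward <- function(x, train = FALSE) {
    s <- op_gap(x)                                        # squeeze: (N, C)
    s <- op_silu(op_dense(s, self$params$w1, self$params$b1))
    s <- op_sigmoid(op_dense(s, self$params$w2, self$params$b2))
    op_gate_channels(x, s)                                # excitation rescale
  }
  self
}

#' Squeeze-and-excitation forward pass
#'
#' Global average pool, fully-connected `c -> c/r`, SiLU, fully-connected
#' `c/r -> c`, sigmoid, then per-channel rescaling of the input.
#'
#' @param x feature map `(H, W, N, C)`.
#' @param cfg an [se_config()] with `channels == C`.
#' @param params optional layer from `nn_se(cfg)`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map of the same shape as `x`.
#' @export
se_forward <- function(x, cfg, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  if (dim(x)[4] != cfg$channels)
    stop(sprintf("input has %d channels but cfg expects %d", dim(x)[4], cfg$channels), call. = FALSE)
  layer <- if (is.null(params)) with_seed(seed, nn_se(cfg)) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

# Standard residual bottleneck: two convs with expansion e (hidden = c2 * e),
# kernels k = c(k1, k2), identity shortcut when channels match.
nn_bottleneck <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 1.0) {
  self <- new_layer("bottleneck")
  ch <- as.integer(round(c2 * e))
  self$children$cv1 <- nn_conv(c1, ch, k[1])
  self$children$cv2 <- nn_conv(ch, c2, k[2])
  self$shortcut <- shortcut && c1 == c2
  self$forward <- function(x, train = FALSE) {
    y <- self$children$cv2$forward(self$children$cv1$forward(x, train), train)
    if (self$shortcut) op_add(x, y) else y
  }
  self
}

# Wavelet bottleneck: the bottleneck convolutions are replaced by WTConv
# operators, each followed by batch normalization + SiLU; identity shortcut.
# `replace` = "both" swaps both convolutions (default, the text's plural);
# "second" keeps a standard 3x3 first convolution (kept for calibration).
nn_bottleneck_wt <- function(c, wtcfg = NULL, shortcut = TRUE, replace = "both") {
  self <- new_layer("bottleneck_wt")
  if (is.null(wtcfg)) wtcfg <- wtconv_config(c)
  if (wtcfg$channels != c) wtcfg <- wtconv_config(c, wtcfg$kernel_size, wtcfg$num_levels, wtcfg$include_base_path)
  wt_unit <- function() {
    u <- new_layer("wt_unit")
    u$children$wt <- nn_wtconv(wtcfg)
    u$params$gamma <- tn_param(rep(1, c))
    u$params$beta <- tn_param(rep(0, c))
    u$bn_state <- new.env(parent = emptyenv())
    u$bn_state$running_mean <- rep(0, c)
    u$bn_state$running_var <- rep(1, c)
    u$forward <- function(x, train = FALSE) {
      y <- u$children$wt$forward(x, train)
      y <- op_batchnorm(y, u$params$gamma, u$params$beta, u$bn_state, train)
      op_silu(y)
    }
    u
  }
  if (identical(replace, "both")) {
    self$children$cv1 <- wt_unit()
    self$children$cv2 <- wt_unit()
  } else {
    self$children$cv1 <- nn_conv(c, c, 3L)
    self$children$cv2 <- wt_unit()
  }
  self$shortcut <- shortcut
  self$forward <- function(x, train = FALSE) {
    y <- self$children$cv2$forward(self$children$cv1$forward(x, train), train)
    if (self$shortcut) op_add(x, y) else y
  }
  self
}

#' Wavelet-bottleneck forward pass
#'
#' Two successive WTConv operators (normalization + SiLU after each) with an
#' identity shortcut; input and output channel counts are equal.
#'
#' @param x feature map `(H, W, N, C)`.
#' @param wtcfg a [wtconv_config()] for the inner operators (default
#'   `wtconv_config(C)`).
#' @param params optional layer from `nn_bottleneck_wt()`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map of the same shape as `x`.
#' @export
bottleneck_wt_forward <- function(x, wtcfg = NULL, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params)) with_seed(seed, nn_bottleneck_wt(dim(x)[4], wtcfg)) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

# Three-conv split block (C3k): cv1/cv2 1x1 to hidden, a chain of `n`
# bottlenecks on the cv1 path, 1x1 fuse.  Hidden width = c2/2.  The wavelet
# variant uses Bottleneck_WT inner units.
nn_c3k <- function(c1, c2, n = 2L, wt = FALSE, wtcfg = NULL, replace = "both") {
  self <- new_layer("c3k")
  ch <- c2 %/% 2L
  self$children$cv1 <- nn_conv(c1, ch, 1L)
  self$children$cv2 <- nn_conv(c1, ch, 1L)
  self$children$cv3 <- nn_conv(2L * ch, c2, 1L)
  for (i in seq_len(n)) {
    self$children[[paste0("m", i)]] <-
      if (wt) nn_bottleneck_wt(ch, wtcfg, replace = replace)
      else nn_bottleneck(ch, ch, k = c(3L, 3L), e = 1.0)
  }
  self$n <- n
  self$forward <- function(x, train = FALSE) {
    a <- self$children$cv1$forward(x, train)
    for (i in seq_len(self$n)) a <- self$children[[paste0("m", i)]]$forward(a, train)
    b <- self$children$cv2$forward(x, train)
    self$children$cv3$forward(op_concat_c(list(a, b)), train)
  }
  self
}

# Split-transform-concat stage (C3k2 / C3K2_WT): 1x1 to 2*hidden, split in
# two, `repeats` inner units each appending its output, 1x1 fuse of all
# chunks.  Inner unit is a C3k (2 bottlenecks) when c3k = TRUE, otherwise a
# single bottleneck; `wt` swaps the bottleneck convolutions for WTConv.
nn_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5, wt = FALSE,
                    wtcfg = NULL, replace = "both", shortcut = TRUE) {
  if (!e %in% c(0.25, 0.5)) stop("expansion e must be 0.25 or 0.5", call. = FALSE)
  self <- new_layer(if (wt) "c3k2_wt" else "c3k2")
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  ch <- as.integer(c2 * e)
  self$ch <- ch; self$n <- n
  self$children$cv1 <- nn_conv(c1, 2L * ch, 1L)
  self$children$cv2 <- nn_conv((2L + n) * ch, c2, 1L)
  for (i in seq_len(n)) {
    self$children[[paste0("m", i)]] <-
      if (c3k) nn_c3k(ch, ch, 2L, wt = wt, wtcfg = wtcfg, replace = replace)
      else if (wt) nn_bottleneck_wt(ch, wtcfg, shortcut = shortcut, replace = replace)
      else nn_bottleneck(ch, ch, shortcut = shortcut, k = c(3L, 3L), e = 1.0)
  }
  self$forward <- function(x, train = FALSE) {
    y <- self$children$cv1$forward(x, train)
    chunks <- list(op_slice_c(y, 1L, self$ch),
                   op_slice_c(y, self$ch + 1L, 2L * self$ch))
    cur <- chunks[[2]]
    for (i in seq_len(self$n)) {
      cur <- self$children[[paste0("m", i)]]$forward(cur, train)
      chunks[[length(chunks) + 1L]] <- cur
    }
    self$children$cv2$forward(op_concat_c(chunks), train)
  }
  self
}

#' C3K2 / C3K2_WT forward pass
#'
#' Functional front-end over the split-transform-concat stage.
#'
#' @param x feature map `(H, W, N, C)`.
#' @param out_channels output channel count.
#' @param repeats number of inner units.
#' @param c3k use a C3K inner block (two chained bottlenecks) instead of a
#'   single bottleneck.
#' @param e hidden expansion, 0.25 or 0.5.
#' @param wt replace the bottleneck convolutions with WTConv operators.
#' @param wtcfg a [wtconv_config()] for the WT variant.
#' @param params optional prebuilt layer from `nn_c3k2()`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map with `out_channels` channels, spatial size unchanged.
#' @export
c3k2_wt_forward <- function(x, out_channels, repeats = 1L, c3k = FALSE, e = 0.5,
                            wt = TRUE, wtcfg = NULL, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params))
    with_seed(seed, nn_c3k2(dim(x)[4], out_channels, repeats, c3k, e, wt, wtcfg))
  else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

# Spatial pyramid pooling (fast): 1x1 c -> c/2, three chained 5x5 max-pools
# (effective windows 5 / 9 / 13), concat of the four maps, 1x1 2c -> c.
nn_sppf <- function(c1, c2) {
  self <- new_layer("sppf")
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  ch <- c1 %/% 2L
  self$children$cv1 <- nn_conv(c1, ch, 1L)
  self$children$cv2 <- nn_conv(4L * ch, c2, 1L)
  self$forward <- function(x, train = FALSE) {
    a <- self$children$cv1$forward(x, train)
    p1 <- op_maxpool(a, 5L, 1L, 2L)
    p2 <- op_maxpool(p1, 5L, 1L, 2L)
    p3 <- op_maxpool(p2, 5L, 1L, 2L)
    self$children$cv2$forward(op_concat_c(list(a, p1, p2, p3)), train)
  }
  self
}

#' Spatial pyramid pooling (fast) forward pass
#' @param x feature map `(H, W, N, C)`.
#' @param params optional layer from `nn_sppf()`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map of the same shape as `x`.
#' @export
sppf_forward <- function(x, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params)) with_seed(seed, nn_sppf(dim(x)[4], dim(x)[4])) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

# Multi-head self-attention on flattened spatial tokens, with a depthwise 3x3
# positional convolution on the value path (baseline C2PSA internals).
nn_attention <- function(dim_c, num_heads, attn_ratio = 0.5) {
  self <- new_layer("attention")
  head_dim <- dim_c %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  nh_kd <- key_dim * num_heads
  h <- dim_c + nh_kd * 2L
  self$num_heads <- num_heads; self$key_dim <- key_dim; self$head_dim <- head_dim
  self$scale <- key_dim^-0.5
  self$children$qkv <- nn_conv(dim_c, h, 1L, act = FALSE)
  self$children$proj <- nn_conv(dim_c, dim_c, 1L, act = FALSE)
  self$children$pe <- nn_conv(dim_c, dim_c, 3L, act = FALSE, groups = dim_c)
  self$forward <- function(x, train = FALSE) {
    d <- fm_dims(x)
    H <- d[1]; W <- d[2]; N <- d[3]
    qkv <- self$children$qkv$forward(x, train)
    per_head <- 2L * self$key_dim + self$head_dim
    # channel layout is head-major: [q_h, k_h, v_h] per head
    v_slices <- lapply(seq_len(self$num_heads), function(hh) {
      off <- (hh - 1L) * per_head
      op_slice_c(qkv, off + 2L * self$key_dim + 1L, off + per_head)
    })
    v_full <- if (length(v_slices) == 1L) v_slices[[1]] else op_concat_c(v_slices)
    pe <- self$children$pe$forward(v_full, train)
    out_mats <- vector("list", N)
    for (n in seq_len(N)) {
      head_outs <- vector("list", self$num_heads)
      for (hh in seq_len(self$num_heads)) {
        off <- (hh - 1L) * per_head
        q <- op_image_mat(op_slice_c(qkv, off + 1L, off + self$key_dim), n)
        kk <- op_image_mat(op_slice_c(qkv, off + self$key_dim + 1L, off + 2L * self$key_dim), n)
        vv <- op_image_mat(v_slices[[hh]], n)
        attn <- op_softmax_rows(op_scalar_mul(op_matmul(q, op_transpose(kk)), self$scale))
        head_outs[[hh]] <- op_matmul(attn, vv)
      }
      out_mats[[n]] <- if (length(head_outs) == 1L) head_outs[[1]] else {
        # column-bind head outputs into (T, dim_c)
        m <- head_outs[[1]]
        for (hh in 2:length(head_outs)) {
          a <- m; b <- head_outs[[hh]]
          ca <- ncol(tn_value(a)); cb <- ncol(tn_value(b))
          m <- tn_op(cbind(tn_value(a), tn_value(b)), list(as_tn(a), as_tn(b)),
                     local({ ca <- ca; cb <- cb
                       function(g) list(g[, seq_len(ca), drop = FALSE],
                                        g[, ca + seq_len(cb), drop = FALSE]) }))
        }
        m
      }
    }
    attended <- op_stack_images(out_mats, H, W, dim_c)
    self$children$proj$forward(op_add(attended, pe), train)
  }
  self
}

# Position-sensitive attention block: attention + 2x feed-forward, both with
# residual shortcuts.
nn_psablock <- function(c) {
  self <- new_layer("psablock")
  self$children$attn <- nn_attention(c, num_heads = max(1L, c %/% 64L))
  self$children$ffn <- nn_seq(nn_conv(c, 2L * c, 1L), nn_conv(2L * c, c, 1L, act = FALSE))
  self$forward <- function(x, train = FALSE) {
    x <- op_add(x, self$children$attn$forward(x, train))
    op_add(x, self$children$ffn$forward(x, train))
  }
  self
}

nn_c2psa <- function(c, n = 1L) {
  self <- new_layer("c2psa")
  c <- as.integer(c)
  ch <- c %/% 2L
  self$ch <- ch; self$n <- n
  self$children$cv1 <- nn_conv(c, 2L * ch, 1L)
  self$children$cv2 <- nn_conv(2L * ch, c, 1L)
  for (i in seq_len(n)) self$children[[paste0("m", i)]] <- nn_psablock(ch)
  self$forward <- function(x, train = FALSE) {
    y <- self$children$cv1$forward(x, train)
    a <- op_slice_c(y, 1L, self$ch)
    b <- op_slice_c(y, self$ch + 1L, 2L * self$ch)
    for (i in seq_len(self$n)) b <- self$children[[paste0("m", i)]]$forward(b, train)
    self$children$cv2$forward(op_concat_c(list(a, b)), train)
  }
  self
}

#' Partial self-attention block forward pass
#' @param x feature map `(H, W, N, C)`.
#' @param params optional layer from `nn_c2psa()`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map of the same shape as `x`.
#' @export
c2psa_forward <- function(x, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params)) with_seed(seed, nn_c2psa(dim(x)[4])) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

# Anchor-free detection head: per scale, a box branch emitting 4 * reg_max
# distribution-focal logits and a class branch emitting `nc` logits.
nn_detect <- function(chs, nc = 6L, reg_max = 16L) {
  self <- new_layer("detect")
  c2 <- max(16L, chs[1] %/% 4L, 4L * reg_max)
  c3 <- max(chs[1], min(nc, 100L))
  self$nc <- nc; self$reg_max <- reg_max
  for (i in seq_along(chs)) {
    ch <- chs[i]
    self$children[[paste0("box", i)]] <- nn_seq(
      nn_conv(ch, c2, 3L), nn_conv(c2, c2, 3L),
      nn_conv(c2, 4L * reg_max, 1L, act = FALSE, bn = FALSE, bias = TRUE))
    self$children[[paste0("cls", i)]] <- nn_seq(
      nn_conv(ch, c3, 3L), nn_conv(c3, c3, 3L),
      nn_conv(c3, nc, 1L, act = FALSE, bn = FALSE, bias = TRUE))
    # bias priors: box distributions start near zero offsets, class scores
    # near a 1% prior so early training is not swamped by negatives
    self$children[[paste0("box", i)]]$children$m3$params$b$v <- rep(1, 4L * reg_max)
    self$children[[paste0("cls", i)]]$children$m3$params$b$v <- rep(stats::qlogis(0.01), nc)
  }
  self$forward <- function(xs, train = FALSE) {
    lapply(seq_along(xs), function(i) {
      op_concat_c(list(self$children[[paste0("box", i)]]$forward(xs[[i]], train),
                       self$children[[paste0("cls", i)]]$forward(xs[[i]], train)))
    })
  }
  self
}

#' Detection head forward pass
#'
#' @param features list of three feature maps at strides 8 / 16 / 32.
#' @param nc number of classes (default 6).
#' @param reg_max number of distribution-focal bins per box side (default 16).
#' @param params optional layer from `nn_detect()`.
#' @param seed RNG seed for the default initialisation.
#' @return list of raw prediction maps, each `(H, W, N, 4*reg_max + nc)`.
#' @export
detect_forward <- function(features, nc = 6L, reg_max = 16L, params = NULL, seed = 0L) {
  if (length(features) != 3L) stop("expected exactly three feature-map scales", call. = FALSE)
  features <- lapply(features, .as_fm)
  chs <- vapply(features, function(f) dim(f)[4], numeric(1))
  layer <- if (is.null(params)) with_seed(seed, nn_detect(as.integer(chs), nc, reg_max)) else params
  no_grad(lapply(layer$forward(lapply(features, tn_leaf)), tn_value))
}

#' Survey WTConv configurations against reference stage parameter counts
#'
#' The reference layer table lists four C3K2_WT stage parameter counts that
#' cannot be reproduced from any configuration stated alongside it.  This
#' report enumerates candidate configurations (kernel size, level count,
#' which bottleneck convolutions are replaced, scales on/off), computes each
#' candidate's four-stage counts with the parameter enumerator, and reports
#' deviations from the targets, flagging the closest candidate.  It never
#' adopts a match silently.
#'
#' @param targets integer vector of four reference stage counts (default:
#'   the reference table's `26080, 103360, 293632, 1127936`).
#' @param kernels,levels candidate grids.
#' @return a data.frame report, one row per candidate plus a baseline
#'   (non-wavelet) reference row; attribute `"closest"` names the candidate
#'   with the smallest total absolute deviation.
#' @export
calibrate_wtconv_config <- function(targets = c(26080L, 103360L, 293632L, 1127936L),
                                    kernels = c(3L, 5L, 7L), levels = 1:3) {
  stopifnot(length(targets) == 4L)
  # the four backbone stages at width multiplier 0.5:
  stages <- list(list(c1 = 64L, c2 = 128L, c3k = FALSE, e = 0.25),
                 list(c1 = 128L, c2 = 256L, c3k = FALSE, e = 0.25),
                 list(c1 = 256L, c2 = 256L, c3k = TRUE, e = 0.5),
                 list(c1 = 512L, c2 = 512L, c3k = TRUE, e = 0.5))
  count_stage <- function(st, wt, wtcfg_fn, replace) {
    ch <- as.integer(st$c2 * st$e)
    blk <- with_seed(0L, nn_c3k2(st$c1, st$c2, 1L, st$c3k, st$e, wt = wt,
                                 wtcfg = if (wt) wtcfg_fn(ch) else NULL,
                                 replace = replace))
    param_count(blk)
  }
  rows <- list()
  base_counts <- vapply(stages, count_stage, numeric(1), wt = FALSE,
                        wtcfg_fn = NULL, replace = "both")
  rows[[1]] <- data.frame(candidate = "baseline (no WTConv)", kernel = NA_integer_,
                          levels = NA_integer_, replace = NA_character_, scales = NA,
                          stage1 = base_counts[1], stage2 = base_counts[2],
                          stage3 = base_counts[3], stage4 = base_counts[4],
                          dev1 = abs(base_counts[1] - targets[1]),
                          dev2 = abs(base_counts[2] - targets[2]),
                          dev3 = abs(base_counts[3] - targets[3]),
                          dev4 = abs(base_counts[4] - targets[4]),
                          stringsAsFactors = FALSE)
  for (k in kernels) for (L in levels) for (repl in c("both", "second")) for (sc in c(TRUE, FALSE)) {
    wtcfg_fn <- local({
      k <- k; L <- L
      function(ch) wtconv_config(ch, k, L)
    })
    counts <- vapply(stages, count_stage, numeric(1), wt = TRUE,
                     wtcfg_fn = wtcfg_fn, replace = repl)
    if (!sc) {
      # scales off: subtract one scalar per channel per path from each WTConv
      scale_params <- function(ch) (1L + 4L * L) * ch
      n_wt_per_stage <- vapply(stages, function(st) {
        units <- if (st$c3k) 2L else 1L     # bottlenecks per stage
        per_bn <- if (repl == "both") 2L else 1L
        units * per_bn
      }, numeric(1))
      chs <- vapply(stages, function(st) as.integer(st$c2 * st$e), numeric(1))
      # c3k inner bottlenecks act on ch/2 channels
      chs_eff <- ifelse(vapply(stages, function(st) st$c3k, logical(1)), chs %/% 2L, chs)
      counts <- counts - n_wt_per_stage * vapply(chs_eff, scale_params, numeric(1))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      candidate = sprintf("k=%d L=%d replace=%s scales=%s", k, L, repl, if (sc) "on" else "off"),
      kernel = k, levels = L, replace = repl, scales = sc,
      stage1 = counts[1], stage2 = counts[2], stage3 = counts[3], stage4 = counts[4],
      dev1 = abs(counts[1] - targets[1]), dev2 = abs(counts[2] - targets[2]),
      dev3 = abs(counts[3] - targets[3]), dev4 = abs(counts[4] - targets[4]),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report$total_dev <- report$dev1 + report$dev2 + report$dev3 + report$dev4
  cand <- report[report$candidate != "baseline (no WTConv)", ]
  attr(report, "closest") <- cand$candidate[which.min(cand$total_dev)]
  attr(report, "targets") <- targets
  report
}
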