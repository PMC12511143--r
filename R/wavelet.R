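# Orthonormal 2-D Haar analysis / synthesis and the wavelet-transform
# convolution (WTConv) operator: per-level depthwise convolutions applied to
# the four frequency bands, recomposed through the inverse transform.
#
# Convention: separable 1-D analysis filters (1,1)/sqrt(2) and (1,-1)/sqrt(2),
# stride 2.  The transform is orthogonal, so it conserves energy and its
# adjoint equals its inverse (which also gives the autograd backward for free).

# Internal: x is (H, W, N, C) with even H, W; returns (H/2, W/2, N, 4C) with
# band order LL, LH, HL, HH (each C channels).  The filter bank reduces to
# 2x2 block combinations (a +- b +- c +- d)/2.
.haar_fwd <- function(x) {
  d <- dim(x)
  y <- haar_fwd_cpp(x, d[1], d[2], d[3], d[4])
  dim(y) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], 4L * d[4])
  y
}

# Inverse: bands (h, w, N, 4C) -> (2h, 2w, N, C).
.haar_inv <- function(b) {
  d <- dim(b)
  C <- d[4] %/% 4L
  y <- haar_inv_cpp(b, d[1], d[2], d[3], C)
  dim(y) <- c(2L * d[1], 2L * d[2], d[3], C)
  y
}

op_haar_dwt <- function(x) {
  xn <- as_tn(x)
  tn_op(.haar_fwd(xn$v), list(xn), function(g) list(.haar_inv(g)))
}

op_haar_idwt <- function(b) {
  bn <- as_tn(b)
  tn_op(.haar_inv(bn$v), list(bn), function(g) list(.haar_fwd(g)))
}

.as_fm <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("input must be a 2-D matrix or a (H, W, N, C) array", call. = FALSE)
  x
}

#' 2-D orthonormal Haar wavelet decomposition
#'
#' Splits a feature map into low-frequency (`LL`) and horizontal / vertical /
#' diagonal high-frequency (`LH`, `HL`, `HH`) bands at half resolution, using
#' the orthonormal Haar filters `(1, 1)/sqrt(2)` and `(1, -1)/sqrt(2)` with
#' stride 2.  Odd spatial sizes are first padded by edge replication; the
#' amount of padding is recorded in the `"pad"` attribute of the result so
#' that [haar_idwt2()] can restore the original size exactly.
#'
#' @param x a numeric matrix `(H, W)` or array `(H, W, N, C)`
#'   (height, width, batch, channels).
#' @return a list with elements `LL`, `LH`, `HL`, `HH` (arrays at half the
#'   padded resolution, same batch/channel dims as `x`) and attribute `"pad"`
#'   giving the `(bottom, right)` edge padding applied.
#' @examples
#' b <- haar_dwt2(matrix(1:16, 4, 4))
#' max(abs(haar_idwt2(b) - matrix(1:16, 4, 4)))
#' @seealso [haar_idwt2()], [wtconv()]
#' @export
haar_dwt2 <- function(x) {
  x <- .as_fm(x)
  d <- dim(x)
  if (any(d[1:2] <= 0) || length(x) == 0) stop("empty input or non-positive dimensions", call. = FALSE)
  pad <- c(d[1] %% 2L, d[2] %% 2L)
  if (any(pad > 0L)) x <- tn_value(op_pad_edge(tn_leaf(x), pad[1], pad[2]))
  b <- .haar_fwd(x)
  d2 <- dim(b)
  C <- d2[4] %/% 4L
  block <- d2[1] * d2[2] * d2[3]
  bandlist <- lapply(1:4, function(i) {
    v <- b[(block * C * (i - 1L) + 1L):(block * C * i)]
    dim(v) <- c(d2[1], d2[2], d2[3], C)
    v
  })
  names(bandlist) <- c("LL", "LH", "HL", "HH")
  attr(bandlist, "pad") <- pad
  bandlist
}

#' 2-D orthonormal Haar wavelet reconstruction
#'
#' Exact inverse of [haar_dwt2()].  Accepts either the list returned by
#' [haar_dwt2()] or the four band arrays individually.
#'
#' @param LL low-frequency band, or a band list from [haar_dwt2()].
#' @param LH,HL,HH high-frequency bands (ignored when `LL` is a band list).
#' @param pad integer `(bottom, right)` edge padding to undo; defaults to the
#'   `"pad"` attribute when present.
#' @return the reconstructed array at doubled (minus padding) resolution.
#' @export
haar_idwt2 <- function(LL, LH = NULL, HL = NULL, HH = NULL, pad = NULL) {
  if (is.list(LL)) {
    if (is.null(pad)) pad <- attr(LL, "pad")
    bands <- LL
    LL <- bands$LL; LH <- bands$LH; HL <- bands$HL; HH <- bands$HH
  }
  LL <- .as_fm(LL); LH <- .as_fm(LH); HL <- .as_fm(HL); HH <- .as_fm(HH)
  dims <- list(dim(LL), dim(LH), dim(HL), dim(HH))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("the four bands must have identical shapes", call. = FALSE)
  b <- c(LL, LH, HL, HH)
  d <- dim(LL)
  dim(b) <- c(d[1], d[2], d[3], 4L * d[4])
  y <- .haar_inv(b)
  if (!is.null(pad) && any(pad > 0L)) {
    y <- y[seq_len(dim(y)[1] - pad[1]), seq_len(dim(y)[2] - pad[2]), , , drop = FALSE]
  }
  y
}

#' WTConv configuration
#'
#' Depthwise wavelet-transform convolution settings.  The operator applies a
#' small `kernel_size` depthwise convolution to each frequency band of an
#' `num_levels`-deep Haar pyramid (plus, optionally, a depthwise convolution
#' at full resolution), so its one-dimensional receptive field grows as
#' `2^L * (k - 1) + 1` while the parameter count grows only linearly in the
#' number of levels.
#'
#' @param channels number of input (= output) channels.
#' @param kernel_size odd depthwise kernel size (default 5).
#' @param num_levels number of wavelet levels, `>= 1` (default 1).
#' @param include_base_path apply a depthwise convolution at full resolution
#'   in parallel with the wavelet cascade (default `TRUE`).
#' @return an object of class `wtconv_config`.
#' @export
wtconv_config <- function(channels, kernel_size = 5L, num_levels = 1L,
                          include_base_path = TRUE) {
  channels <- as.integer(channels)
  kernel_size <- as.integer(kernel_size)
  num_levels <- as.integer(num_levels)
  if (channels < 1L) stop("channels must be >= 1", call. = FALSE)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) stop("kernel_size must be odd and positive", call. = FALSE)
  if (num_levels < 1L) stop("num_levels must be >= 1", call. = FALSE)
  structure(list(channels = channels, kernel_size = kernel_size,
                 num_levels = num_levels, include_base_path = isTRUE(include_base_path)),
            class = "wtconv_config")
}

#' Learnable-parameter count of a WTConv operator
#'
#' Depthwise kernels are bias-free and every path carries one scalar scale per
#' channel: the base path holds `k^2 * C + C` parameters and each wavelet
#' level `4 C k^2 + 4 C` (the four bands are convolved jointly with
#' `4 C` depthwise groups).  The count is linear in `num_levels` even though
#' the receptive field ([wtconv_receptive_field()]) doubles per level.
#'
#' @param cfg a [wtconv_config()].
#' @return integer parameter total.
#' @examples
#' wtconv_param_count(wtconv_config(32, 5, 1))  # 4160
#' @export
wtconv_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "wtconv_config"))
  k2 <- cfg$kernel_size^2
  base <- if (cfg$include_base_path) k2 * cfg$channels + cfg$channels else 0
  per_level <- 4 * cfg$channels * k2 + 4 * cfg$channels
  as.integer(base + cfg$num_levels * per_level)
}

#' One-dimensional receptive field of the deepest wavelet path
#'
#' The span of input pixels influencing one output pixel through `L` rounds of
#' DWT / depthwise convolution / IWT is `2^L * (k - 1) + 1`; `L = 0` (base
#' path only) degenerates to `k`.
#'
#' @param cfg a [wtconv_config()], or a list with `kernel_size`/`num_levels`.
#' @param num_levels optional override of the level count (e.g. 0 for the
#'   degenerate base-only case).
#' @return integer receptive-field width in pixels.
#' @export
wtconv_receptive_field <- function(cfg, num_levels = NULL) {
  L <- if (is.null(num_levels)) cfg$num_levels else num_levels
  as.integer(2^L * (cfg$kernel_size - 1L) + 1L)
}

# WTConv layer (see nn.R for the layer infrastructure).
nn_wtconv <- function(cfg) {
  self <- new_layer("wtconv")
  self$cfg <- cfg
  C <- cfg$channels; k <- cfg$kernel_size
  if (cfg$include_base_path) {
    self$params$base_w <- tn_param(init_kaiming(c(k, k, C), fan_in = k * k))
    self$params$base_s <- tn_param(rep(1, C))
  }
  for (i in seq_len(cfg$num_levels)) {
    self$params[[paste0("lvl", i, "_w")]] <- tn_param(init_kaiming(c(k, k, 4L * C), fan_in = k * k))
    self$params[[paste0("lvl", i, "_s")]] <- tn_param(rep(1, 4L * C))
  }
  self$forward <- function(x, train = FALSE) {
    d <- fm_dims(x)
    if (d[4] != C) stop(sprintf("wtconv expects %d channels, got %d", C, d[4]), call. = FALSE)
    L <- cfg$num_levels
    lls <- vector("list", L); highs <- vector("list", L); sizes <- vector("list", L)
    cur <- as_tn(x)
    for (i in seq_len(L)) {
      dc <- fm_dims(cur)
      sizes[[i]] <- dc[1:2]
      if (dc[1] %% 2L || dc[2] %% 2L) cur <- op_pad_edge(cur, dc[1] %% 2L, dc[2] %% 2L)
      bands <- op_haar_dwt(cur)
      conv <- op_scale_channels(
        op_dwconv2d(bands, self$params[[paste0("lvl", i, "_w")]], 1L, k %/% 2L),
        self$params[[paste0("lvl", i, "_s")]])
      lls[[i]] <- op_slice_c(conv, 1L, C)
      highs[[i]] <- op_slice_c(conv, C + 1L, 4L * C)
      cur <- op_slice_c(bands, 1L, C)
    }
    rec <- NULL
    for (i in rev(seq_len(L))) {
      ll <- if (is.null(rec)) lls[[i]] else op_add(lls[[i]], rec)
      rec <- op_haar_idwt(op_concat_c(list(ll, highs[[i]])))
      rec <- op_crop(rec, sizes[[i]][1], sizes[[i]][2])
    }
    if (cfg$include_base_path) {
      base <- op_scale_channels(op_dwconv2d(as_tn(x), self$params$base_w, 1L, k %/% 2L),
                                self$params$base_s)
      rec <- op_add(base, rec)
    }
    rec
  }
  self
}

#' Apply a wavelet-transform convolution to a feature map
#'
#' Functional front-end over the WTConv layer: a depthwise `k x k`
#' convolution (with per-channel scale) at full resolution, plus one
#' depthwise convolution per wavelet level acting jointly on the four Haar
#' bands, recomposed from the deepest level upward through the inverse
#' transform.  Stride is never carried by the cascade itself; output shape
#' equals input shape.
#'
#' @param x feature map `(H, W, N, C)` (a matrix is promoted).
#' @param cfg a [wtconv_config()]; `cfg$channels` must match `x`.
#' @param params optional layer created by `nn_wtconv(cfg)` whose kernels are
#'   to be reused; defaults to a fresh deterministic initialisation.
#' @param seed RNG seed for the default initialisation.
#' @return array of the same shape as `x`.
#' @export
wtconv <- function(x, cfg, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params)) with_seed(seed, nn_wtconv(cfg)) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}
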