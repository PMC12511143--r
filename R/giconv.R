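# Ghost-Inception downsampling convolution (GIConv) and its analytic
# multiply-accumulate cost model.
#
# A primary k x k strided convolution produces a half-width "core" map
# (c_in -> n/2 channels); a four-branch Inception block then derives
# multi-scale features from the core map (n/2 -> n/2 channels) and the two
# are concatenated into the n-channel output.  Every convolution is
# bias-free with per-channel normalization and SiLU.

#' GIConv configuration
#'
#' @param in_channels input channel count.
#' @param out_channels output channel count `n`; must be divisible by 8 so the
#'   Inception branch widths `n/2 * (1/4, 1/8, 1/4)` are integral.
#' @param kernel_size odd kernel size of the primary convolution (default 3).
#' @param stride stride of the primary convolution (default 2; the Inception
#'   branches are always stride 1).
#' @return an object of class `giconv_config`.
#' @export
giconv_config <- function(in_channels, out_channels, kernel_size = 3L, stride = 2L) {
  out_channels <- as.integer(out_channels)
  if (out_channels %% 8L != 0L)
    stop("out_channels must be divisible by 8 (branch widths n/2 * {1/4, 1/8} must be integral)",
         call. = FALSE)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels), out_channels = out_channels,
                 kernel_size = as.integer(kernel_size), stride = as.integer(stride)),
            class = "giconv_config")
}

# Four-branch Inception block on c channels (c divisible by 8):
#   1: 1x1 c -> c/4
#   2: 1x1 c -> c/8, 3x3 c/8 -> c/4
#   3: 1x1 c -> c/8, 3x3 c/8 -> c/4, 3x3 c/4 -> c/4
#   4: 3x3 max-pool (stride 1, pad 1), 1x1 c -> c/4
nn_inception <- function(c) {
  if (c %% 8L != 0L) stop("inception channel count must be divisible by 8", call. = FALSE)
  self <- new_layer("inception")
  q <- c %/% 4L; e <- c %/% 8L
  self$children$b1 <- nn_conv(c, q, 1L)
  self$children$b2 <- nn_seq(nn_conv(c, e, 1L), nn_conv(e, q, 3L))
  self$children$b3 <- nn_seq(nn_conv(c, e, 1L), nn_conv(e, q, 3L), nn_conv(q, q, 3L))
  self$children$b4 <- nn_conv(c, q, 1L)
  self$forward <- function(x, train = FALSE) {
    pooled <- op_maxpool(x, 3L, 1L, 1L)
    op_concat_c(list(self$children$b1$forward(x, train),
                     self$children$b2$forward(x, train),
                     self$children$b3$forward(x, train),
                     self$children$b4$forward(pooled, train)))
  }
  self
}

nn_giconv <- function(cfg) {
  self <- new_layer("giconv")
  self$cfg <- cfg
  half <- cfg$out_channels %/% 2L
  self$children$primary <- nn_conv(cfg$in_channels, half, cfg$kernel_size, cfg$stride)
  self$children$inception <- nn_inception(half)
  self$forward <- function(x, train = FALSE) {
    core <- self$children$primary$forward(x, train)
    # concat order: core map first, then branches 1-4
    op_concat_c(list(core, self$children$inception$forward(core, train)))
  }
  self
}

#' Multi-branch Inception forward pass
#'
#' Applies the four parallel branches (1x1; 1x1 then 3x3; 1x1 then two 3x3;
#' 3x3 max-pool then 1x1) and concatenates their `c/4`-channel outputs, so the
#' output channel count equals the input's at unchanged spatial size.
#'
#' @param x feature map `(H, W, N, C)` with `C` divisible by 8.
#' @param params optional layer from `nn_inception()`; a fresh deterministic
#'   initialisation is used otherwise.
#' @param seed RNG seed for the default initialisation.
#' @return feature map with the same dimensions as `x`.
#' @export
inception_forward <- function(x, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  layer <- if (is.null(params)) with_seed(seed, nn_inception(dim(x)[4])) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

#' Ghost-Inception convolution forward pass
#'
#' @param x feature map `(H, W, N, C)` with `C == cfg$in_channels`.
#' @param cfg a [giconv_config()].
#' @param params optional layer from `nn_giconv(cfg)`.
#' @param seed RNG seed for the default initialisation.
#' @return feature map with `cfg$out_channels` channels at `(H/stride, W/stride)`.
#' @export
giconv_forward <- function(x, cfg, params = NULL, seed = 0L) {
  x <- .as_fm(x)
  if (dim(x)[4] != cfg$in_channels)
    stop(sprintf("input has %d channels but cfg expects %d", dim(x)[4], cfg$in_channels),
         call. = FALSE)
  layer <- if (is.null(params)) with_seed(seed, nn_giconv(cfg)) else params
  no_grad(tn_value(layer$forward(tn_leaf(x))))
}

#' Analytic multiply-accumulate cost of the Inception block
#'
#' Per-branch MAC totals at spatial size `H x w` and channel count `c`:
#' `(1/4, 13/32, 31/32, 1/4) * H * w * c^2`, summing to `(15/8) * H * w * c^2`.
#' Only convolutions count; normalization, activation and pooling are free by
#' convention.
#'
#' @param H,w spatial size at which the block runs.
#' @param c channel count.
#' @return a `cost_report` list with per-branch and total MACs.
#' @examples
#' inception_cost(1, 1, 32)$macs_total  # 1920 = (15/8) * 32^2
#' @export
inception_cost <- function(H, w, c) {
  stopifnot(H > 0, w > 0, c > 0)
  hw <- as.double(H) * w
  b <- hw * c^2 * c(1 / 4, 13 / 32, 31 / 32, 1 / 4)
  structure(list(macs_branch1 = b[1], macs_branch2 = b[2], macs_branch3 = b[3],
                 macs_branch4 = b[4], macs_total = sum(b),
                 spatial = c(H = H, w = w), channels = c),
            class = "cost_report")
}

#' Analytic cost report of a GIConv layer versus a standard convolution
#'
#' Primary-path MACs are `out_H * out_W * (n/2) * k^2 * c_in`; the Inception
#' block adds [inception_cost()] at `n/2` channels.  The reference standard
#' convolution costs `out_H * out_W * n * k^2 * c_in`, giving the ratio
#' `S = 1/2 + 15 n / (32 k^2 c_in)` (see [cost_ratio()]), independent of
#' spatial size.
#'
#' @param cfg a [giconv_config()].
#' @param out_H,out_W output spatial size.
#' @return a `cost_report` list with fields `macs_primary`,
#'   `macs_branch1..4`, `macs_total`, `macs_standard`, `ratio_S`.
#' @export
giconv_cost <- function(cfg, out_H, out_W) {
  half <- cfg$out_channels / 2
  hw <- as.double(out_H) * out_W
  primary <- hw * half * cfg$kernel_size^2 * cfg$in_channels
  inc <- inception_cost(out_H, out_W, half)
  total <- primary + inc$macs_total
  standard <- hw * cfg$out_channels * cfg$kernel_size^2 * cfg$in_channels
  structure(list(macs_primary = primary,
                 macs_branch1 = inc$macs_branch1, macs_branch2 = inc$macs_branch2,
                 macs_branch3 = inc$macs_branch3, macs_branch4 = inc$macs_branch4,
                 macs_total = total, macs_standard = standard,
                 ratio_S = total / standard,
                 spatial = c(H = out_H, w = out_W),
                 channels = cfg$in_channels),
            class = "cost_report")
}

#' Closed-form GIConv-to-standard-convolution computation ratio
#'
#' `S = 1/2 + 15 n / (32 k^2 c)`: the fraction of a standard `k x k`
#' convolution's MACs needed by GIConv with `n` output and `c` input channels.
#' At `k = 3` and `n = 2c` this is `0.60417`, i.e. roughly 60%.
#'
#' @param k kernel size of the primary / reference convolution.
#' @param n output channels.
#' @param c input channels.
#' @return the ratio as a plain number.
#' @examples
#' cost_ratio(3, 64, 32)  # 0.604...
#' @export
cost_ratio <- function(k, n, c) {
  stopifnot(k > 0, n > 0, c > 0)
  1 / 2 + 15 * n / (32 * k^2 * c)
}

#' Count the convolution MACs of a forward pass by instrumentation
#'
#' Runs `fn()` with the multiply-accumulate counter enabled and returns the
#' number of MACs performed by convolution, dense and matrix-multiply ops
#' (normalization, activations and pooling contribute nothing).
#'
#' @param fn a zero-argument function executing the forward pass.
#' @return MAC count (double).
#' @export
count_macs <- function(fn) {
  mac_counter_start()
  on.exit(mac_counter_stop())
  fn()
  macs <- .giwt$macs
  macs
}

#' Relative reduction between two cost figures, in percent
#'
#' `100 * (baseline - improved) / baseline`; used e.g. to express a GFLOPs
#' saving relative to a baseline model.
#'
#' @param baseline,improved positive numbers on the same scale.
#' @return percentage reduction.
#' @examples
#' cost_reduction_percent(21.6, 18.7)  # 13.4
#' @export
cost_reduction_percent <- function(baseline, improved) {
  100 * (baseline - improved) / baseline
}
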