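# Layer infrastructure.  A layer is an environment with a `forward(x, train)`
# closure, its own `params` (named list of parameter tensors), `children`
# (sub-layers) and, for batch normalization, running-statistics buffers.
# Construction order fixes the RNG draw order, so building under a seed is
# deterministic.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$children <- list()
  e$params <- list()
  class(e) <- c(paste0("giwt_", kind), "giwt_layer")
  e
}

init_kaiming <- function(dims, fan_in) {
  b <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

#' Collect the parameter tensors of a layer (recursively)
#' @param layer a layer object
#' @param prefix name prefix for nested parameters
#' @return named list of parameter tensors
#' @keywords internal
collect_params <- function(layer, prefix = "") {
  out <- list()
  for (nm in names(layer$params)) {
    out[[paste0(prefix, nm)]] <- layer$params[[nm]]
  }
  for (nm in names(layer$children)) {
    out <- c(out, collect_params(layer$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count the learnable parameters of a layer or model
#'
#' Enumerates every parameter tensor (convolution kernels, normalization
#' scale/shift pairs, biases, attention projections) of the layer and its
#' sub-layers.  Batch-normalization running statistics are buffers, not
#' parameters, and are excluded.
#'
#' @param layer a layer built by one of the `nn_*` constructors or a model
#'   from [build_model()].
#' @return integer total.
#' @export
param_count <- function(layer) {
  if (!is.null(layer$layers)) {  # assembled model
    return(as.integer(sum(vapply(layer$layers, param_count, numeric(1)))))
  }
  ps <- collect_params(layer)
  as.integer(sum(vapply(ps, function(p) length(p$v), numeric(1))))
}

# Standard convolution block: bias-free kernel + per-channel batch
# normalization (2 parameters per channel) + SiLU.  This convention is pinned
# by the reference stem-layer count 3*32*9 + 2*32 = 928.
nn_conv <- function(cin, cout, k = 1L, stride = 1L, pad = NULL, act = TRUE,
                    bn = TRUE, bias = FALSE, groups = 1L) {
  self <- new_layer("conv")
  cin <- as.integer(cin); cout <- as.integer(cout)
  k <- as.integer(k)
  if (is.null(pad)) pad <- k %/% 2L
  self$cin <- cin; self$cout <- cout; self$k <- k
  self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$depthwise <- (groups == cin && cin == cout && groups > 1L)
  if (groups != 1L && !self$depthwise) stop("only groups == 1 or depthwise supported", call. = FALSE)
  if (self$depthwise) {
    self$params$w <- tn_param(init_kaiming(c(k, k, cin), fan_in = k * k))
  } else {
    self$params$w <- tn_param(init_kaiming(c(k, k, cin, cout), fan_in = k * k * cin))
  }
  if (bn) {
    self$params$gamma <- tn_param(rep(1, cout))
    self$params$beta <- tn_param(rep(0, cout))
    self$bn_state <- new.env(parent = emptyenv())
    self$bn_state$running_mean <- rep(0, cout)
    self$bn_state$running_var <- rep(1, cout)
  }
  if (bias) self$params$b <- tn_param(rep(0, cout))
  self$act <- act; self$bn <- bn; self$bias <- bias
  self$forward <- function(x, train = FALSE) {
    y <- if (self$depthwise) op_dwconv2d(x, self$params$w, self$stride, self$pad)
         else op_conv2d(x, self$params$w, self$stride, self$pad)
    if (self$bn) y <- op_batchnorm(y, self$params$gamma, self$params$beta, self$bn_state, train)
    if (self$bias) y <- op_bias_channels(y, self$params$b)
    if (self$act) y <- op_silu(y)
    y
  }
  self
}

# Sequential container.
nn_seq <- function(...) {
  self <- new_layer("seq")
  self$children <- list(...)
  names(self$children) <- paste0("m", seq_along(self$children))
  self$forward <- function(x, train = FALSE) {
    for (ch in self$children) x <- ch$forward(x, train)
    x
  }
  self
}

# SGD with momentum and decoupled-from-BN weight decay; params is a named
# list of parameter tensors.  Velocity buffers live alongside the parameters.
sgd_step <- function(params, lr, momentum = 0.937, weight_decay = 5e-4) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    # weight decay on multi-dim kernels / dense weights only, not on
    # normalization parameters, scales or biases
    if (!is.null(dim(p$v)) && length(dim(p$v)) >= 2L && weight_decay > 0) {
      g <- g + weight_decay * p$v
    }
    if (is.null(p$vel)) p$vel <- g * 0
    p$vel <- momentum * p$vel + g
    p$v <- p$v - lr * p$vel
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Serialize / restore parameter values and BN buffers of a model.
model_state <- function(model) {
  ps <- lapply(collect_model_params(model), function(p) p$v)
  bns <- list()
  walk <- function(layer, prefix) {
    if (!is.null(layer$bn_state)) {
      bns[[prefix]] <<- list(mean = layer$bn_state$running_mean,
                             var = layer$bn_state$running_var)
    }
    for (nm in names(layer$children)) walk(layer$children[[nm]], paste0(prefix, nm, "."))
  }
  if (!is.null(model$layers)) {
    for (i in seq_along(model$layers)) walk(model$layers[[i]], paste0("L", i, "."))
  } else walk(model, "")
  list(params = ps, bn = bns)
}

load_model_state <- function(model, state) {
  ps <- collect_model_params(model)
  stopifnot(identical(names(ps), names(state$params)))
  for (nm in names(ps)) ps[[nm]]$v <- state$params[[nm]]
  walk <- function(layer, prefix) {
    if (!is.null(layer$bn_state) && !is.null(state$bn[[prefix]])) {
      layer$bn_state$running_mean <- state$bn[[prefix]]$mean
      layer$bn_state$running_var <- state$bn[[prefix]]$var
    }
    for (nm in names(layer$children)) walk(layer$children[[nm]], paste0(prefix, nm, "."))
  }
  if (!is.null(model$layers)) {
    for (i in seq_along(model$layers)) walk(model$layers[[i]], paste0("L", i, "."))
  } else walk(model, "")
  invisible(model)
}

collect_model_params <- function(model) {
  if (!is.null(model$layers)) {
    out <- list()
    for (i in seq_along(model$layers)) {
      out <- c(out, collect_params(model$layers[[i]], paste0("L", i, ".")))
    }
    out
  } else collect_params(model)
}
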