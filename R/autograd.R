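#' @useDynLib giwtnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode tape autograd over plain numeric arrays.  A tensor node is an
# environment holding the value, an accumulated gradient, its parents, and a
# backward closure mapping the node's gradient to parent gradients.  Graph
# recording is switched off during inference (see `no_grad()`), in which case
# ops behave as plain array functions wrapped in leaf nodes.

.giwt <- new.env(parent = emptyenv())
.giwt$grad_enabled <- TRUE
.giwt$node_counter <- 0L
.giwt$count_macs <- FALSE
.giwt$macs <- 0

tn_leaf <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- NULL
  e$bw <- NULL
  e$track <- FALSE
  class(e) <- "giwt_tensor"
  e
}

#' @keywords internal
tn_param <- function(v, name = NULL) {
  e <- tn_leaf(v)
  e$track <- TRUE
  e$is_param <- TRUE
  e$name <- name
  e
}

# Record an op result.  `bw` receives the output gradient and returns a list of
# gradients aligned with `parents` (NULL entries allowed for untracked parents).
tn_op <- function(v, parents, bw) {
  if (!.giwt$grad_enabled) return(tn_leaf(v))
  track <- any(vapply(parents, function(p) isTRUE(p$track), logical(1)))
  e <- tn_leaf(v)
  if (track) {
    e$track <- TRUE
    e$parents <- parents
    e$bw <- bw
    .giwt$node_counter <- .giwt$node_counter + 1L
    e$id <- .giwt$node_counter
  }
  e
}

as_tn <- function(x) if (inherits(x, "giwt_tensor")) x else tn_leaf(x)

tn_value <- function(x) if (inherits(x, "giwt_tensor")) x$v else x

#' Evaluate an expression with gradient recording disabled
#' @param expr expression to evaluate
#' @keywords internal
no_grad <- function(expr) {
  old <- .giwt$grad_enabled
  .giwt$grad_enabled <- FALSE
  on.exit(.giwt$grad_enabled <- old)
  force(expr)
}

# Topologically ordered backward pass from a scalar root.
tn_backward <- function(root) {
  stopifnot(length(root$v) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (is.null(node$id)) next
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (isTRUE(p$track) && !is.null(p$id) && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  root$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$bw) || is.null(node$grad)) next
    grads <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      g <- grads[[j]]
      if (is.null(g) || !isTRUE(p$track)) next
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    # free graph memory as soon as a node has been consumed: its value,
    # closure (which captures forward intermediates) and gradient are no
    # longer needed once its parents have received their contributions
    if (!isTRUE(node$is_param)) {
      node$grad <- NULL
      node$v <- NULL
    }
    node$bw <- NULL
    node$parents <- NULL
  }
  invisible(root)
}

# Multiply-accumulate instrumentation: conv/dense ops add their MAC counts here
# when enabled; normalization, activations and pooling contribute nothing.
mac_counter_start <- function() {
  .giwt$count_macs <- TRUE
  .giwt$macs <- 0
}

mac_counter_stop <- function() {
  .giwt$count_macs <- FALSE
  .giwt$macs
}

mac_add <- function(n) {
  if (.giwt$count_macs) .giwt$macs <- .giwt$macs + n
  invisible(NULL)
}

# Run an expression under a fixed RNG state, restoring the caller's state.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
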