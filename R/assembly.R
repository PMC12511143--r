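# Full detector assembly: backbone (Conv stem, 4 x GIConv downsampling
# interleaved with C3K2_WT stages, SPPF, C2PSA), top-down + bottom-up fusion
# neck with C3K2_WT fusion blocks, squeeze-and-excitation attention per
# exported scale, and the anchor-free detection head at strides 8/16/32.

#' Network specification
#'
#' Describes the detector graph.  Channel widths follow the small-model
#' convention (width multiplier 0.5 of the base widths 64-1024, capped at
#' 1024); `width` rescales them for reduced smoke-test variants.
#'
#' @param width channel width multiplier (0.5 = standard small model;
#'   0.25 = fast CPU smoke variant).
#' @param nc number of object classes (default 6).
#' @param wt_kernel,wt_levels WTConv depthwise kernel size and wavelet level
#'   count used inside every C3K2_WT stage.
#' @param use_wt use wavelet bottlenecks in the C3k2 stages (default TRUE;
#'   FALSE gives the plain baseline stages).
#' @param use_giconv replace the strided downsampling convolutions with
#'   GIConv (default TRUE).
#' @param se_reduction SE bottleneck reduction ratio (default 16).
#' @param se_position `"neck_head"` (default: one SE per exported scale,
#'   after neck fusion, before the head) or `"backbone"` (SE on the backbone
#'   taps; kept for placement comparisons) or `"none"`.
#' @param reg_max distribution-focal bins per box side (default 16).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(width = 0.5, nc = 6L, wt_kernel = 5L, wt_levels = 1L,
                         use_wt = TRUE, use_giconv = TRUE,
                         se_reduction = 16L, se_position = c("neck_head", "backbone", "none"),
                         reg_max = 16L) {
  se_position <- match.arg(se_position)
  ch <- function(base) as.integer(max(8L, round(base * width / 8) * 8))
  structure(list(width = width, nc = as.integer(nc),
                 wt_kernel = as.integer(wt_kernel), wt_levels = as.integer(wt_levels),
                 use_wt = isTRUE(use_wt), use_giconv = isTRUE(use_giconv),
                 se_reduction = as.integer(se_reduction), se_position = se_position,
                 reg_max = as.integer(reg_max),
                 ch = c(c64 = ch(64), c128 = ch(128), c256 = ch(256),
                        c512 = ch(512), c1024 = ch(1024))),
            class = "network_spec")
}

#' Build the detector
#'
#' Deterministically constructs the full model graph under `seed`.  A forward
#' pass on a `(H, W, N, 3)` input yields three raw prediction maps at strides
#' 8, 16 and 32.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed governing all parameter initialisation.
#' @return an object of class `giwt_model`.
#' @export
build_model <- function(spec = network_spec(), seed = 0L) {
  ch <- spec$ch
  wtcfg_for <- function(channels) wtconv_config(channels, spec$wt_kernel, spec$wt_levels)
  down <- function(cin, cout) {
    if (spec$use_giconv) nn_giconv(giconv_config(cin, cout, 3L, 2L))
    else nn_conv(cin, cout, 3L, 2L)
  }
  stage <- function(cin, cout, c3k, e) {
    hid <- as.integer(cout * e)
    inner <- if (c3k) hid %/% 2L else hid
    nn_c3k2(cin, cout, 1L, c3k, e, wt = spec$use_wt,
            wtcfg = if (spec$use_wt) wtcfg_for(inner) else NULL)
  }
  stage_name <- if (spec$use_wt) "C3K2_WT" else "C3k2"
  down_name <- if (spec$use_giconv) "GIConv" else "Conv"
  rows <- list()
  add <- function(name, kind, from, layer = NULL) {
    rows[[length(rows) + 1L]] <<- list(name = name, kind = kind, from = from, layer = layer)
    length(rows)
  }
  model <- new.env(parent = emptyenv())
  with_seed(seed, {
    i1 <- add("Conv", "layer", 0L, nn_conv(3L, ch["c64"], 3L, 2L))
    i2 <- add(down_name, "layer", i1, down(ch["c64"], ch["c128"]))
    i3 <- add(paste0(stage_name, "(P2)"), "layer", i2, stage(ch["c128"], ch["c256"], FALSE, 0.25))
    i4 <- add(down_name, "layer", i3, down(ch["c256"], ch["c256"]))
    i5 <- add(paste0(stage_name, "(P3)"), "layer", i4, stage(ch["c256"], ch["c512"], FALSE, 0.25))
    i6 <- add(down_name, "layer", i5, down(ch["c512"], ch["c512"]))
    i7 <- add(paste0(stage_name, "(P4)"), "layer", i6, stage(ch["c512"], ch["c512"], TRUE, 0.5))
    i8 <- add(down_name, "layer", i7, down(ch["c512"], ch["c1024"]))
    i9 <- add(stage_name, "layer", i8, stage(ch["c1024"], ch["c1024"], TRUE, 0.5))
    i10 <- add("SPPF", "layer", i9, nn_sppf(ch["c1024"], ch["c1024"]))
    i11 <- add("C2PSA(P5)", "layer", i10, nn_c2psa(ch["c1024"], 1L))
    bb_taps <- c(i5, i7, i11)
    if (spec$se_position == "backbone") {
      s1 <- add("SE", "layer", i5, nn_se(se_config(ch["c512"], spec$se_reduction)))
      s2 <- add("SE", "layer", i7, nn_se(se_config(ch["c512"], spec$se_reduction)))
      s3 <- add("SE", "layer", i11, nn_se(se_config(ch["c1024"], spec$se_reduction)))
      bb_taps <- c(s1, s2, s3)
    }
    u1 <- add("Upsample", "upsample", bb_taps[3])
    c1 <- add("Concat", "concat", c(u1, bb_taps[2]))
    f1 <- add(stage_name, "layer", c1, stage(ch["c512"] + ch["c1024"], ch["c512"], FALSE, 0.5))
    u2 <- add("Upsample", "upsample", f1)
    c2 <- add("Concat", "concat", c(u2, bb_taps[1]))
    p3 <- add(stage_name, "layer", c2, stage(ch["c512"] + ch["c512"], ch["c256"], FALSE, 0.5))
    d1 <- add("Conv", "layer", p3, nn_conv(ch["c256"], ch["c256"], 3L, 2L))
    c3 <- add("Concat", "concat", c(d1, f1))
    p4 <- add(stage_name, "layer", c3, stage(ch["c256"] + ch["c512"], ch["c512"], FALSE, 0.5))
    d2 <- add("Conv", "layer", p4, nn_conv(ch["c512"], ch["c512"], 3L, 2L))
    c4 <- add("Concat", "concat", c(d2, bb_taps[3]))
    p5 <- add(stage_name, "layer", c4, stage(ch["c512"] + ch["c1024"], ch["c1024"], TRUE, 0.5))
    taps <- c(p3, p4, p5)
    if (spec$se_position == "neck_head") {
      e1 <- add("SE", "layer", p3, nn_se(se_config(ch["c256"], spec$se_reduction)))
      e2 <- add("SE", "layer", p4, nn_se(se_config(ch["c512"], spec$se_reduction)))
      e3 <- add("SE", "layer", p5, nn_se(se_config(ch["c1024"], spec$se_reduction)))
      taps <- c(e1, e2, e3)
    }
    dd <- add("Detect", "detect", taps,
              nn_detect(c(ch["c256"], ch["c512"], ch["c1024"]), spec$nc, spec$reg_max))
    model$detect_row <- dd
  })
  model$spec <- spec
  model$rows <- rows
  model$layers <- lapply(rows, function(r) r$layer)
  model$layers <- model$layers[!vapply(model$layers, is.null, logical(1))]
  model$strides <- c(8L, 16L, 32L)
  class(model) <- "giwt_model"
  model
}

# Forward pass through the assembled graph.  Returns the three raw prediction
# maps; `keep` optionally returns all cached row outputs.
forward_model <- function(model, x, train = FALSE, keep = FALSE) {
  outs <- vector("list", length(model$rows))
  xin <- as_tn(x)
  for (i in seq_along(model$rows)) {
    r <- model$rows[[i]]
    inp <- lapply(r$from, function(j) if (j == 0L) xin else outs[[j]])
    outs[[i]] <- switch(r$kind,
      layer = r$layer$forward(inp[[1]], train),
      upsample = op_upsample2(inp[[1]]),
      concat = op_concat_c(inp),
      detect = r$layer$forward(inp, train))
  }
  preds <- outs[[model$detect_row]]
  if (keep) attr(preds, "outs") <- outs
  preds
}

#' Predict raw detection maps
#'
#' @param object a model from [build_model()].
#' @param x input array `(H, W, N, 3)` with values in `[0, 1]`, `H` and `W`
#'   divisible by 32.
#' @param ... unused.
#' @return list of three arrays `(H/s, W/s, N, 4*reg_max + nc)` for strides
#'   `s = 8, 16, 32`.
#' @export
predict.giwt_model <- function(object, x, ...) {
  x <- .as_fm(x)
  no_grad(lapply(forward_model(object, tn_leaf(x), train = FALSE), tn_value))
}

#' Per-layer summary of an assembled model
#'
#' Runs a single dummy input through the network, recording each graph row's
#' output spatial size, parameter count, and instrumented convolution /
#' fully-connected multiply-accumulates.  GFLOPs use the 2-FLOPs-per-MAC
#' convention with normalization, activation and pooling excluded.
#'
#' @param model a model from [build_model()].
#' @param input_size input height (= width) in pixels; must be divisible
#'   by 32.
#' @return an object of class `model_summary`: a data.frame of rows plus
#'   `total_params` / `gflops` attributes.
#' @export
summarize <- function(model, input_size = 320L) {
  stopifnot(input_size %% 32L == 0L)
  x <- tn_leaf(array(0.5, dim = c(input_size, input_size, 1L, 3L)))
  n <- length(model$rows)
  sizes <- character(n); macs <- numeric(n)
  outs <- vector("list", n)
  no_grad({
    mac_counter_start()
    prev <- 0
    for (i in seq_len(n)) {
      r <- model$rows[[i]]
      inp <- lapply(r$from, function(j) if (j == 0L) x else outs[[j]])
      outs[[i]] <- switch(r$kind,
        layer = r$layer$forward(inp[[1]], FALSE),
        upsample = op_upsample2(inp[[1]]),
        concat = op_concat_c(inp),
        detect = r$layer$forward(inp, FALSE))
      cur <- .giwt$macs
      macs[i] <- cur - prev
      prev <- cur
      d <- if (r$kind == "detect") fm_dims(outs[[i]][[1]]) else fm_dims(outs[[i]])
      sizes[i] <- paste0(d[1], "x", d[2])
    }
    mac_counter_stop()
  })
  params <- vapply(model$rows, function(r) if (is.null(r$layer)) 0L else param_count(r$layer),
                   integer(1))
  df <- data.frame(layer = seq_len(n),
                   module = vapply(model$rows, `[[`, character(1), "name"),
                   output_size = sizes, params = params, macs = macs,
                   stringsAsFactors = FALSE)
  structure(df, class = c("model_summary", "data.frame"),
            total_params = sum(params), gflops = 2 * sum(macs) / 1e9,
            input_size = input_size)
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("Model summary at %dx%d input\n", attr(x, "input_size"), attr(x, "input_size")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Total parameters: %s   GFLOPs: %.2f\n",
              format(attr(x, "total_params"), big.mark = ","), attr(x, "gflops")))
  invisible(x)
}

#' Reference backbone layer table
#'
#' The published per-layer parameter counts of the backbone at a 320x320
#' input (output sizes 160 down to 10).  Rows whose counts are fully pinned
#' by the stated construction conventions (stem Conv, the four GIConv stages,
#' SPPF) are marked `pinned`; the C3K2_WT and C2PSA rows are reported with
#' deviations instead.
#'
#' @return a data.frame with columns `module`, `output_size`, `params`,
#'   `pinned`.
#' @export
table2_reference <- function() {
  data.frame(
    module = c("Conv", "GIConv", "C3K2_WT(P2)", "GIConv", "C3K2_WT(P3)",
               "GIConv", "C3K2_WT(P4)", "GIConv", "C3K2_WT", "SPPF", "C2PSA(P5)"),
    output_size = c("160x160", "80x80", "80x80", "40x40", "40x40",
                    "20x20", "20x20", "10x10", "10x10", "10x10", "10x10"),
    params = c(928L, 11296L, 26080L, 81728L, 103360L, 326272L, 293632L,
               713984L, 1127936L, 656896L, 990976L),
    pinned = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Compare a model summary against a reference layer table
#'
#' Matches the reference rows against the first backbone rows of the summary
#' (in order) and reports absolute and relative deviations.  The comparison
#' "passes" when every pinned row matches exactly.
#'
#' @param summary a [summarize()] result.
#' @param reference a reference table like [table2_reference()].
#' @return a data.frame diff report with attribute `"pinned_ok"`.
#' @export
compare_to_reference <- function(summary, reference = table2_reference()) {
  if (is.null(reference$params) || is.null(reference$module))
    stop("reference must have 'module' and 'params' columns", call. = FALSE)
  n <- nrow(reference)
  if (nrow(summary) < n) stop("summary has fewer rows than the reference", call. = FALSE)
  actual <- summary$params[seq_len(n)]
  dev <- actual - reference$params
  df <- data.frame(module = reference$module,
                   reference = reference$params,
                   actual = actual,
                   abs_dev = abs(dev),
                   rel_dev = abs(dev) / reference$params,
                   pinned = if (!is.null(reference$pinned)) reference$pinned else FALSE,
                   match = dev == 0L,
                   stringsAsFactors = FALSE)
  attr(df, "pinned_ok") <- all(df$match[df$pinned])
  df
}

#' Total GFLOPs of a model at a given input size
#'
#' @param model a model from [build_model()].
#' @param input_size input height (= width), divisible by 32.
#' @return GFLOPs (2 x instrumented convolution MACs / 1e9).
#' @export
model_gflops <- function(model, input_size = 640L) {
  attr(summarize(model, input_size), "gflops")
}
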