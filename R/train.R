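# Desk-scale training: centre-prior one-to-many assignment, CIoU box loss,
# binary cross-entropy class loss and distribution-focal loss, stochastic
# gradient descent with momentum, cosine-annealed learning rate with linear
# warmup, and loss-based early stopping.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 32, 300 epochs, initial
#' learning rate 0.01, weight decay 0.0005, momentum 0.937, cosine annealing
#' (floor 1% of the initial rate), early stopping after 100 epochs without
#' validation-loss improvement.  Desk-scale runs override `epochs`,
#' `batch_size` and `input_size` downward.
#'
#' @param batch_size images per SGD step.
#' @param epochs training epochs.
#' @param initial_lr initial learning rate.
#' @param weight_decay L2 penalty on convolution / dense kernels.
#' @param momentum SGD momentum factor.
#' @param early_stop_patience epochs of non-improving validation loss before
#'   stopping (strict improvement resets the counter).
#' @param input_size square input size in pixels (divisible by 32).
#' @param warmup_epochs linear learning-rate warmup span.
#' @param lr_floor_frac cosine floor as a fraction of `initial_lr`.
#' @param box_weight,cls_weight,dfl_weight loss component weights.
#' @param augment apply mosaic / mixup augmentation during training.
#' @param mosaic_p,mixup_p augmentation probabilities.
#' @param seed RNG seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 300L, initial_lr = 0.01,
                         weight_decay = 5e-4, momentum = 0.937,
                         early_stop_patience = 100L, input_size = 640L,
                         warmup_epochs = 3L, lr_floor_frac = 0.01,
                         box_weight = 7.5, cls_weight = 0.5, dfl_weight = 1.5,
                         augment = TRUE, mosaic_p = 1.0, mixup_p = 0.15,
                         seed = 0L) {
  stopifnot(batch_size > 0, epochs > 0, initial_lr > 0, input_size %% 32 == 0,
            early_stop_patience <= epochs)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 momentum = momentum, early_stop_patience = as.integer(early_stop_patience),
                 input_size = as.integer(input_size), warmup_epochs = warmup_epochs,
                 lr_floor_frac = lr_floor_frac, box_weight = box_weight,
                 cls_weight = cls_weight, dfl_weight = dfl_weight,
                 augment = isTRUE(augment), mosaic_p = mosaic_p, mixup_p = mixup_p,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(E) = floor + (lr0 - floor) * (1 + cos(pi * E / E_max)) / 2`; equals
#' `lr0` at epoch 0 and decays to the floor at `E_max`.
#'
#' @param epoch current epoch (0-based; fractional values allowed).
#' @param epochs total epochs.
#' @param initial_lr starting rate.
#' @param floor final rate (default 1% of `initial_lr`).
#' @return learning rate.
#' @export
cosine_lr <- function(epoch, epochs, initial_lr = 0.01, floor = initial_lr * 0.01) {
  floor + (initial_lr - floor) * (1 + cos(pi * pmin(epoch, epochs) / epochs)) / 2
}

# Scale selection by box size: small boxes go to stride 8, medium to 16,
# large to 32 (thresholds on the longer side, in input pixels).
.scale_for_size <- function(size, input_size) {
  cuts <- input_size * c(0.1875, 0.5)   # 48 / 128 px at a 256 input
  ifelse(size <= cuts[1], 1L, ifelse(size <= cuts[2], 2L, 3L))
}

# Centre-prior one-to-many assignment.  For every ground-truth box: pick the
# scale by size, mark the centre cell plus 8-neighbour cells whose centres
# fall inside the box as positives.  Cell conflicts keep the smaller box.
# Returns, per scale, a data.frame of positives (row/col/image 0-based, class,
# ltrb distances in stride units).
assign_targets <- function(gt_list, input_size, strides = c(8L, 16L, 32L),
                           reg_max = 16L) {
  pos <- lapply(strides, function(s) NULL)
  area_map <- lapply(strides, function(s) list())
  for (n in seq_along(gt_list)) {
    b <- gt_list[[n]]
    if (is.null(b) || nrow(b) == 0L) next
    for (i in seq_len(nrow(b))) {
      bw <- b$x2[i] - b$x1[i]; bh <- b$y2[i] - b$y1[i]
      if (bw <= 0 || bh <= 0) next
      si <- .scale_for_size(max(bw, bh), input_size)
      s <- strides[si]
      grid <- input_size %/% s
      cx <- (b$x1[i] + b$x2[i]) / 2; cy <- (b$y1[i] + b$y2[i]) / 2
      cc <- min(grid - 1L, max(0L, floor(cx / s)))
      cr <- min(grid - 1L, max(0L, floor(cy / s)))
      cells <- expand.grid(r = (cr - 1L):(cr + 1L), c = (cc - 1L):(cc + 1L))
      cells <- cells[cells$r >= 0 & cells$r < grid & cells$c >= 0 & cells$c < grid, ]
      ctr_x <- (cells$c + 0.5) * s; ctr_y <- (cells$r + 0.5) * s
      inside <- ctr_x > b$x1[i] & ctr_x < b$x2[i] & ctr_y > b$y1[i] & ctr_y < b$y2[i]
      keep <- inside | (cells$r == cr & cells$c == cc)
      cells <- cells[keep, , drop = FALSE]
      ctr_x <- (cells$c + 0.5) * s; ctr_y <- (cells$r + 0.5) * s
      eps <- 0.01
      df <- data.frame(
        r = cells$r, c = cells$c, n = n - 1L, cls = b$class_id[i],
        l = pmin(pmax((ctr_x - b$x1[i]) / s, 0), reg_max - 1 - eps),
        t = pmin(pmax((ctr_y - b$y1[i]) / s, 0), reg_max - 1 - eps),
        rr = pmin(pmax((b$x2[i] - ctr_x) / s, 0), reg_max - 1 - eps),
        bb = pmin(pmax((b$y2[i] - ctr_y) / s, 0), reg_max - 1 - eps),
        area = bw * bh)
      pos[[si]] <- rbind(pos[[si]], df)
    }
  }
  # resolve duplicate cells: keep the smallest box (small-object priority)
  for (si in seq_along(pos)) {
    p <- pos[[si]]
    if (is.null(p) || nrow(p) == 0L) next
    key <- paste(p$r, p$c, p$n)
    p <- p[order(p$area), ]
    p <- p[!duplicated(paste(p$r, p$c, p$n)), ]
    pos[[si]] <- p
  }
  pos
}

# Composite detection loss on raw prediction tensors (training graph).
detection_loss <- function(preds, targets, nc, reg_max, cfg) {
  total_pos <- sum(vapply(targets, function(p) if (is.null(p)) 0L else nrow(p), integer(1)))
  norm <- max(1L, total_pos)
  bins <- matrix(seq_len(reg_max) - 1, reg_max, 1)
  loss_cls <- NULL; loss_box <- NULL; loss_dfl <- NULL
  for (si in seq_along(preds)) {
    pr <- preds[[si]]
    d <- fm_dims(pr)
    H <- d[1]; W <- d[2]; N <- d[3]
    M <- H * W * N
    pm <- op_reshape(pr, c(M, d[4]))
    p <- targets[[si]]
    npos <- if (is.null(p)) 0L else nrow(p)
    cls_target <- matrix(0, M, nc)
    if (npos > 0L) {
      rows <- p$r + H * p$c + H * W * p$n + 1L
      cls_target[cbind(rows, p$cls + 1L)] <- 1
    }
    cls_logits <- op_cols(pm, 4L * reg_max + 1L, d[4])
    lc <- op_bce_sum(cls_logits, cls_target, 1)
    loss_cls <- if (is.null(loss_cls)) lc else op_add(loss_cls, lc)
    if (npos == 0L) next
    P <- op_gather_rows(pm, rows)
    box_logits <- op_cols(P, 1L, 4L * reg_max)              # (npos, 64) bin-major
    flat <- op_reshape(box_logits, c(npos * 4L, reg_max))   # rows (pos, side)
    tvec <- c(p$l, p$t, p$rr, p$bb)
    ld <- op_dfl_sum(flat, tvec, 1 / 4)
    loss_dfl <- if (is.null(loss_dfl)) ld else op_add(loss_dfl, ld)
    # expected distances and CIoU against the target boxes (stride units)
    probs <- op_softmax_rows(flat)
    dist <- op_reshape(op_matmul(probs, bins), c(npos, 4L))
    s <- c(8L, 16L, 32L)[si]
    ctr_x <- (p$c + 0.5); ctr_y <- (p$r + 0.5)              # stride units
    px1 <- op_sub(tn_leaf(ctr_x), op_col(dist, 1L))
    py1 <- op_sub(tn_leaf(ctr_y), op_col(dist, 2L))
    px2 <- op_add(tn_leaf(ctr_x), op_col(dist, 3L))
    py2 <- op_add(tn_leaf(ctr_y), op_col(dist, 4L))
    gx1 <- ctr_x - p$l; gy1 <- ctr_y - p$t
    gx2 <- ctr_x + p$rr; gy2 <- ctr_y + p$bb
    lb <- op_dot_const(ciou_loss(px1, py1, px2, py2, gx1, gy1, gx2, gy2),
                       rep(1, npos))
    loss_box <- if (is.null(loss_box)) lb else op_add(loss_box, lb)
  }
  zero <- tn_leaf(0)
  loss_cls <- op_scalar_mul(if (is.null(loss_cls)) zero else loss_cls, 1 / norm)
  loss_box <- op_scalar_mul(if (is.null(loss_box)) zero else loss_box, 1 / norm)
  loss_dfl <- op_scalar_mul(if (is.null(loss_dfl)) zero else loss_dfl, 1 / norm)
  total <- op_add(op_add(op_scalar_mul(loss_box, cfg$box_weight),
                         op_scalar_mul(loss_cls, cfg$cls_weight)),
                  op_scalar_mul(loss_dfl, cfg$dfl_weight))
  list(total = total, box = tn_value(loss_box), cls = tn_value(loss_cls),
       dfl = tn_value(loss_dfl))
}

# Complete-IoU loss per box pair (vectors of corners; g* are constants).
ciou_loss <- function(px1, py1, px2, py2, gx1, gy1, gx2, gy2, eps = 1e-9) {
  pw <- op_clamp_min(op_sub(px2, px1), eps)
  ph <- op_clamp_min(op_sub(py2, py1), eps)
  gw <- gx2 - gx1; gh <- gy2 - gy1
  iw <- op_clamp_min(op_sub(op_pmin2(px2, tn_leaf(gx2)), op_pmax2(px1, tn_leaf(gx1))), 0)
  ih <- op_clamp_min(op_sub(op_pmin2(py2, tn_leaf(gy2)), op_pmax2(py1, tn_leaf(gy1))), 0)
  inter <- op_mul(iw, ih)
  union <- op_scalar_add(op_sub(op_add(op_mul(pw, ph), tn_leaf(gw * gh)), inter), eps)
  iouv <- op_div(inter, union)
  # centre distance over enclosing-box diagonal
  pcx <- op_scalar_mul(op_add(px1, px2), 0.5); pcy <- op_scalar_mul(op_add(py1, py2), 0.5)
  gcx <- (gx1 + gx2) / 2; gcy <- (gy1 + gy2) / 2
  rho2 <- op_add(op_square(op_sub(pcx, tn_leaf(gcx))), op_square(op_sub(pcy, tn_leaf(gcy))))
  cw <- op_sub(op_pmax2(px2, tn_leaf(gx2)), op_pmin2(px1, tn_leaf(gx1)))
  chh <- op_sub(op_pmax2(py2, tn_leaf(gy2)), op_pmin2(py1, tn_leaf(gy1)))
  c2 <- op_scalar_add(op_add(op_square(cw), op_square(chh)), eps)
  # aspect-ratio consistency
  v <- op_scalar_mul(op_square(op_sub(tn_leaf(atan(gw / pmax(gh, eps))),
                                      op_atan(op_div(pw, ph)))), 4 / pi^2)
  alpha <- tn_leaf(tn_value(v) / (1 - tn_value(iouv) + tn_value(v) + eps))
  op_add(op_add(op_scalar_add(op_scalar_mul(iouv, -1), 1), op_div(rho2, c2)),
         op_mul(alpha, v))
}

# Assemble a training batch: returns the input array and per-image box lists
# (in input pixels), applying mosaic / mixup when configured.
make_batch <- function(images, idx, cfg) {
  sz <- cfg$input_size
  n <- length(idx)
  x <- array(0, dim = c(sz, sz, n, 3L))
  gt <- vector("list", n)
  for (j in seq_len(n)) {
    im <- images[[idx[j]]]
    if (cfg$augment && stats::runif(1) < cfg$mosaic_p) {
      others <- sample(seq_along(images), 3L, replace = length(images) < 4L)
      im <- mosaic(images[c(idx[j], others)], c(sz, sz),
                   seed = sample.int(1e9, 1L))
    }
    if (cfg$augment && stats::runif(1) < cfg$mixup_p) {
      other <- images[[sample(seq_along(images), 1L)]]
      if (identical(dim(other$pixels), dim(im$pixels)))
        im <- mixup(im, other, stats::runif(1, 0.3, 0.7))
    }
    d <- dim(im$pixels)
    boxes <- im$boxes
    if (d[1] != sz || d[2] != sz) {
      sy <- sz / d[1]; sx <- sz / d[2]
      im$pixels <- resize_nearest(im$pixels, sz, sz)
      if (nrow(boxes) > 0) {
        boxes$x1 <- boxes$x1 * sx; boxes$x2 <- boxes$x2 * sx
        boxes$y1 <- boxes$y1 * sy; boxes$y2 <- boxes$y2 * sy
      }
    }
    x[, , j, ] <- im$pixels / 255
    gt[[j]] <- boxes
  }
  list(x = x, gt = gt)
}

# One forward/backward/step; returns the loss components.
train_step <- function(model, params, batch, cfg, lr) {
  preds <- forward_model(model, tn_leaf(batch$x), train = TRUE)
  targets <- assign_targets(batch$gt, cfg$input_size, model$strides, model$spec$reg_max)
  loss <- detection_loss(preds, targets, model$spec$nc, model$spec$reg_max, cfg)
  comps <- c(box = loss$box, cls = loss$cls, dfl = loss$dfl)
  if (any(!is.finite(comps))) {
    bad <- names(comps)[which(!is.finite(comps))[1]]
    stop(sprintf("non-finite loss: component '%s' is %s", bad, comps[[bad]]), call. = FALSE)
  }
  tn_backward(loss$total)
  sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
  comps
}

#' Train the detector
#'
#' Deterministic under `config$seed` (up to floating-point non-associativity).
#' Logs per-iteration loss components; early-stops when the validation loss
#' fails to improve for `early_stop_patience` epochs; returns (and optionally
#' saves) the best checkpoint.
#'
#' @param config a [train_config()].
#' @param dataset_dir directory from [make_dataset()], or a list with
#'   elements `train` (and optionally `val`) of `annotated_image` lists.
#' @param spec a [network_spec()] for the model (default: the 0.25-width
#'   smoke variant at the configured input size).
#' @param max_iterations optional hard cap on SGD iterations.
#' @param checkpoint_path optional path; the best model state is saved there
#'   with `saveRDS()`.
#' @param verbose print progress lines.
#' @return list with `model`, `log` (data.frame of loss components and
#'   learning rate), `best_val_loss`, `epochs_run`.
#' @export
train <- function(config, dataset_dir, spec = NULL, max_iterations = Inf,
                  checkpoint_path = NULL, verbose = interactive()) {
  if (is.character(dataset_dir)) {
    imgs <- load_split(dataset_dir, "train")
    val <- tryCatch(load_split(dataset_dir, "val"), error = function(e) NULL)
  } else {
    imgs <- dataset_dir$train
    val <- dataset_dir$val
  }
  if (length(imgs) == 0L) stop("empty training split", call. = FALSE)
  if (is.null(spec)) spec <- network_spec(width = 0.25)
  model <- build_model(spec, seed = config$seed)
  params <- collect_model_params(model)
  iters_per_epoch <- max(1L, ceiling(length(imgs) / config$batch_size))
  total_iters <- min(max_iterations, config$epochs * iters_per_epoch)
  warmup_iters <- config$warmup_epochs * iters_per_epoch
  log <- list()
  best_val <- Inf; best_state <- NULL; bad_epochs <- 0L; it <- 0L; epoch <- 0L
  set.seed(config$seed)
  while (it < total_iters) {
    order_idx <- sample(seq_along(imgs))
    epoch_pos <- 0L
    while (epoch_pos < length(imgs) && it < total_iters) {
      idx <- order_idx[(epoch_pos + 1L):min(epoch_pos + config$batch_size, length(imgs))]
      epoch_pos <- epoch_pos + length(idx)
      it <- it + 1L
      base_lr <- cosine_lr(it / iters_per_epoch, config$epochs, config$initial_lr,
                           config$initial_lr * config$lr_floor_frac)
      lr <- if (it <= warmup_iters && warmup_iters > 0) base_lr * it / warmup_iters else base_lr
      batch <- make_batch(imgs, idx, config)
      comps <- train_step(model, params, batch, config, lr)
      log[[length(log) + 1L]] <- data.frame(iter = it, epoch = epoch,
                                            box = comps["box"], cls = comps["cls"],
                                            dfl = comps["dfl"], lr = lr)
      if (verbose && (it %% 10L == 0L || it == 1L))
        message(sprintf("iter %d  box %.3f  cls %.3f  dfl %.3f  lr %.4g",
                        it, comps["box"], comps["cls"], comps["dfl"], lr))
    }
    epoch <- epoch + 1L
    if (!is.null(val) && length(val) > 0L) {
      vl <- validation_loss(model, val, config)
      if (vl < best_val) {
        best_val <- vl; bad_epochs <- 0L
        best_state <- model_state(model)
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$early_stop_patience) break
      }
    }
  }
  if (!is.null(best_state)) load_model_state(model, best_state)
  result <- list(model = model, log = do.call(rbind, log),
                 best_val_loss = if (is.finite(best_val)) best_val else NA_real_,
                 epochs_run = epoch, config = config, spec = spec)
  if (!is.null(checkpoint_path)) {
    saveRDS(list(state = model_state(model), spec = spec, config = config),
            checkpoint_path)
  }
  result
}

#' Validation loss of a model over a split
#'
#' @param model a model from [build_model()].
#' @param images list of `annotated_image` objects.
#' @param config a [train_config()] (loss weights / input size).
#' @return weighted total loss (scalar).
#' @export
validation_loss <- function(model, images, config) {
  cfg <- config
  cfg$augment <- FALSE
  batch <- make_batch(images, seq_along(images), cfg)
  preds <- lapply(forward_model(model, tn_leaf(batch$x), train = FALSE),
                  function(p) tn_leaf(tn_value(p)))
  targets <- assign_targets(batch$gt, cfg$input_size, model$strides, model$spec$reg_max)
  no_grad({
    loss <- detection_loss(preds, targets, model$spec$nc, model$spec$reg_max, cfg)
    tn_value(loss$total)
  })
}

#' Load a checkpoint written by [train()]
#'
#' @param path checkpoint file.
#' @return the restored model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = 0L)
  load_model_state(model, ck$state)
  model
}

#' Evaluate a model on a dataset split
#'
#' Runs inference with the mAP operating settings (confidence 0.001, NMS IoU
#' 0.7) for the AP sweep and with the reporting settings (confidence 0.25,
#' NMS IoU 0.45) for precision / recall / F1.
#'
#' @param model a model from [build_model()] or a checkpoint path.
#' @param dataset_dir dataset directory or a list of `annotated_image`s.
#' @param split split name when `dataset_dir` is a directory.
#' @param input_size evaluation input size (default: images' own size).
#' @return an `eval_result` (see [map_suite()]).
#' @export
evaluate <- function(model, dataset_dir, split = "val", input_size = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  images <- if (is.character(dataset_dir)) load_split(dataset_dir, split) else dataset_dir
  if (!is.null(input_size)) {
    images <- lapply(images, function(im) {
      d <- dim(im$pixels)
      if (d[1] == input_size && d[2] == input_size) return(im)
      sy <- input_size / d[1]; sx <- input_size / d[2]
      im$pixels <- resize_nearest(im$pixels, input_size, input_size)
      if (nrow(im$boxes) > 0) {
        im$boxes$x1 <- im$boxes$x1 * sx; im$boxes$x2 <- im$boxes$x2 * sx
        im$boxes$y1 <- im$boxes$y1 * sy; im$boxes$y2 <- im$boxes$y2 * sy
      }
      im
    })
  }
  if (model$spec$nc != 6L && length(unique(ground_truth_table(images)$class_id)) > model$spec$nc)
    stop("class-count mismatch between model and dataset", call. = FALSE)
  gts <- ground_truth_table(images)
  dets_map <- detect_objects(model, images, conf_thr = 0.001, nms_iou = 0.7)
  dets_prf <- detect_objects(model, images, conf_thr = 0.25, nms_iou = 0.45)
  res <- map_suite(dets_map, gts, n_classes = model$spec$nc, conf_thr = 0)
  tp <- fp <- fn <- 0L
  for (img in unique(c(dets_prf$image_id, gts$image_id))) {
    m <- match_detections(dets_prf[dets_prf$image_id == img, , drop = FALSE],
                          gts[gts$image_id == img, , drop = FALSE], 0.5)
    tp <- tp + m$tp_count; fp <- fp + m$fp_count; fn <- fn + m$fn_count
  }
  prf <- precision_recall_f1(tp, fp, fn)
  res$precision <- unname(prf["precision"]); res$recall <- unname(prf["recall"])
  res$f1 <- unname(prf["f1"]); res$tp <- tp; res$fp <- fp; res$fn <- fn
  res
}
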