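# Decoding raw anchor-free predictions into detection boxes.
#
# Per scale the head emits 4 * reg_max distribution-focal logits plus `nc`
# class logits per cell.  Box channels are bin-major: side s (1 = left,
# 2 = top, 3 = right, 4 = bottom), bin b occupies channel (b-1)*4 + s.  A
# cell's box side offset is the softmax-expected bin value times the stride;
# a one-hot distribution on bin b therefore decodes to offset b * stride.

#' Decode raw prediction maps into detection boxes
#'
#' @param preds list of three raw prediction arrays
#'   `(H, W, N, 4*reg_max + nc)` at strides 8 / 16 / 32.
#' @param conf_thr minimum class score (sigmoid) to keep a cell.
#' @param nc number of classes.
#' @param reg_max distribution-focal bin count.
#' @param strides stride per scale.
#' @return data.frame `image` (batch index), `class_id`, `x1..y2` (input
#'   pixels), `confidence`.
#' @export
decode_predictions <- function(preds, conf_thr = 0.25, nc = 6L, reg_max = 16L,
                               strides = c(8L, 16L, 32L)) {
  out <- list()
  for (si in seq_along(preds)) {
    p <- preds[[si]]
    d <- dim(p)
    H <- d[1]; W <- d[2]; N <- d[3]
    s <- strides[si]
    M <- H * W * N
    pm <- p; dim(pm) <- c(M, d[4])
    cls_logit <- pm[, 4L * reg_max + seq_len(nc), drop = FALSE]
    score <- 1 / (1 + exp(-cls_logit))
    conf <- apply(score, 1L, max)
    keep <- which(conf >= conf_thr)
    if (length(keep) == 0L) next
    cls <- max.col(score[keep, , drop = FALSE], ties.method = "first") - 1L
    # expected distances from the bin distributions
    box_logit <- pm[keep, seq_len(4L * reg_max), drop = FALSE]
    dim(box_logit) <- c(length(keep), 4L, reg_max)
    dists <- matrix(0, length(keep), 4L)
    for (side in 1:4) {
      lg <- box_logit[, side, ]
      if (is.null(dim(lg))) lg <- matrix(lg, nrow = length(keep))
      e <- exp(lg - apply(lg, 1L, max))
      pr <- e / rowSums(e)
      dists[, side] <- pr %*% (seq_len(reg_max) - 1L)
    }
    # cell centers: row index h -> y, column index w -> x (0-based pixels)
    lin <- keep - 1L
    h <- lin %% H
    w <- (lin %/% H) %% W
    n <- lin %/% (H * W)
    cx <- (w + 0.5) * s
    cy <- (h + 0.5) * s
    out[[length(out) + 1L]] <- data.frame(
      image = n + 1L, class_id = cls,
      x1 = cx - dists[, 1] * s, y1 = cy - dists[, 2] * s,
      x2 = cx + dists[, 3] * s, y2 = cy + dists[, 4] * s,
      confidence = conf[keep])
  }
  if (length(out) == 0L)
    return(data.frame(image = integer(0), class_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      confidence = numeric(0)))
  do.call(rbind, out)
}

#' Run the detector on images and return final detections
#'
#' Forward pass, decoding, confidence filtering and per-class NMS.
#'
#' @param model a model from [build_model()].
#' @param images list of `annotated_image` objects (or plain `(H, W, 3)`
#'   pixel arrays in `[0, 255]`), all of the model's input size.
#' @param conf_thr confidence threshold.
#' @param nms_iou per-class NMS IoU threshold.
#' @param batch_size images per forward pass.
#' @return data.frame of detections with `image_id` keys.
#' @export
detect_objects <- function(model, images, conf_thr = 0.25, nms_iou = 0.45,
                           batch_size = 8L) {
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  px <- lapply(images, function(im) if (is.list(im)) im$pixels else im)
  res <- list()
  for (start in seq(1L, length(px), by = batch_size)) {
    batch <- start:min(start + batch_size - 1L, length(px))
    d <- dim(px[[batch[1]]])
    x <- array(0, dim = c(d[1], d[2], length(batch), 3L))
    for (j in seq_along(batch)) x[, , j, ] <- px[[batch[j]]] / 255
    preds <- predict(model, x)
    dets <- decode_predictions(preds, conf_thr, model$spec$nc, model$spec$reg_max)
    for (j in seq_along(batch)) {
      di <- dets[dets$image == j, , drop = FALSE]
      if (nrow(di) == 0L) next
      di <- nms(di, nms_iou)
      di$image_id <- ids[batch[j]]
      res[[length(res) + 1L]] <- di[, c("image_id", "class_id", "x1", "y1", "x2",
                                        "y2", "confidence")]
    }
  }
  if (length(res) == 0L)
    return(data.frame(image_id = character(0), class_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      confidence = numeric(0)))
  do.call(rbind, res)
}

#' Write / read detections as JSON lines
#'
#' One JSON object per line with fields `image_id`, `class_id`, `x1`, `y1`,
#' `x2`, `y2`, `confidence`.
#'
#' @param dets detections data.frame (as from [detect_objects()]).
#' @param path file path.
#' @return `path` invisibly; `read_detections_jsonl()` returns the
#'   data.frame.
#' @export
write_detections_jsonl <- function(dets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(dets))) {
    writeLines(jsonlite::toJSON(as.list(dets[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(image_id = character(0), class_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      confidence = numeric(0)))
  do.call(rbind, lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l))))
}

#' Ground-truth table of a dataset split
#'
#' @param images list of `annotated_image` objects with `boxes` and ids.
#' @return data.frame with `image_id`, `class_id`, `x1..y2`.
#' @export
ground_truth_table <- function(images) {
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    b <- images[[i]]$boxes
    if (nrow(b) == 0L) return(NULL)
    data.frame(image_id = ids[i], class_id = b$class_id,
               x1 = b$x1, y1 = b$y1, x2 = b$x2, y2 = b$y2)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(image_id = character(0), class_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0)))
  do.call(rbind, rows)
}
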