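# Detection evaluation: IoU, confidence-ordered greedy matching, precision /
# recall / F1, per-class average precision with 101-point interpolation, and
# the mAP@50 / mAP@50~95 suite over IoU thresholds 0.50 to 0.95.
#
# Detections and ground truths are data.frames with columns
#   image_id, class_id, x1, y1, x2, y2 [, confidence]
# using 0-based pixel corner coordinates with x2 > x1, y2 > y1.

#' Intersection over union of two boxes
#'
#' @param a,b numeric vectors `(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @return overlap ratio in `[0, 1]`; 0 for disjoint boxes.  A degenerate
#'   zero-area box yields 0 with a warning.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  if ((a[3] - a[1]) * (a[4] - a[2]) <= 0 || (b[3] - b[1]) * (b[4] - b[2]) <= 0) {
    warning("degenerate zero-area box; IoU defined as 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# Vectorised IoU of one box against a matrix of boxes (rows).
iou_one_many <- function(a, B) {
  if (nrow(B) == 0L) return(numeric(0))
  iw <- pmin(a[3], B[, 3]) - pmax(a[1], B[, 1])
  ih <- pmin(a[4], B[, 4]) - pmax(a[2], B[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Match detections to ground truths within one image
#'
#' Detections are taken in decreasing confidence order; each claims the
#' highest-IoU not-yet-matched same-class ground truth with IoU at or above
#' the threshold.  One match per ground truth; unmatched detections are false
#' positives, unmatched ground truths false negatives.
#'
#' @param dets data.frame with `class_id`, `x1..y2`, `confidence`.
#' @param gts data.frame with `class_id`, `x1..y2`.
#' @param iou_thr IoU threshold (default 0.5).
#' @return list with logical `tp` flags (aligned to `dets` in the original
#'   row order), the matched gt index per detection (NA for FP), and counts
#'   `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  nd <- nrow(dets)
  tp <- logical(nd)
  match_idx <- rep(NA_integer_, nd)
  gt_taken <- logical(nrow(gts))
  ord <- order(-dets$confidence)
  gt_boxes <- as.matrix(gts[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  for (i in ord) {
    cand <- which(!gt_taken & gts$class_id == dets$class_id[i])
    if (length(cand) == 0L) next
    ious <- iou_one_many(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                         gt_boxes[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      tp[i] <- TRUE
      match_idx[i] <- cand[j]
      gt_taken[cand[j]] <- TRUE
    }
  }
  list(tp = tp, match_idx = match_idx,
       tp_count = sum(tp), fp_count = sum(!tp), fn_count = sum(!gt_taken))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the convention
#' `0/0 = 0`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector `(precision, recall, f1)` as fractions.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from a precision / recall pair
#'
#' Harmonic mean `2PR/(P+R)`; works identically on fractions or percentages,
#' so published percentage pairs can be checked directly.
#'
#' @param precision,recall values on a common scale.
#' @return F1 on the same scale.
#' @examples
#' round(f1_score(84.7, 82.2), 1)  # 83.4
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Average precision of one class from flagged detection records
#'
#' Area under the precision-recall curve.  The default follows the modern
#' detector convention: the precision envelope (running maximum from the
#' right) sampled at the 101 recall points 0, 0.01, ..., 1.00.  The exact
#' all-point envelope integral is available via `interpolation = "exact"`.
#'
#' @param tp logical TP flags sorted by decreasing confidence.
#' @param gt_count number of ground-truth boxes of the class.
#' @param interpolation `"101point"` (default) or `"exact"`.
#' @return AP in `[0, 1]`; 0 when there are no detections.
#' @export
average_precision <- function(tp, gt_count, interpolation = c("101point", "exact")) {
  interpolation <- match.arg(interpolation)
  if (gt_count <= 0) stop("gt_count must be positive; empty classes are excluded upstream", call. = FALSE)
  if (length(tp) == 0L) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / gt_count
  precision <- ctp / (ctp + cfp)
  # precision envelope: best precision achievable at recall >= r
  env <- rev(cummax(rev(precision)))
  if (interpolation == "101point") {
    rs <- seq(0, 1, by = 0.01)
    pr <- vapply(rs, function(r) {
      i <- which(recall >= r)
      if (length(i) == 0L) 0 else env[i[1]]
    }, numeric(1))
    mean(pr)
  } else {
    r_prev <- c(0, recall)
    sum((recall - r_prev[-length(r_prev)]) * env)
  }
}

# Flatten per-image matching into class-wise sorted TP flag vectors at one
# IoU threshold.
class_records <- function(dets, gts, class_id, iou_thr) {
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  if (nrow(d) == 0L) return(logical(0))
  flags <- logical(nrow(d))
  k <- 0L
  for (img in unique(d$image_id)) {
    di <- d[d$image_id == img, , drop = FALSE]
    gi <- gts[gts$image_id == img & gts$class_id == class_id, , drop = FALSE]
    m <- match_detections(di, gi, iou_thr)
    flags[k + seq_len(nrow(di))] <- m$tp[order(-di$confidence)]
    k <- k + nrow(di)
  }
  # flags above are per-image confidence-sorted blocks; resort globally
  confs <- unlist(lapply(unique(d$image_id), function(img) {
    sort(d$confidence[d$image_id == img], decreasing = TRUE)
  }))
  flags[order(-confs)]
}

#' Full detection-metric suite
#'
#' Computes per-class AP at the ten IoU thresholds 0.50, 0.55, ..., 0.95,
#' mAP@50 (class-mean AP at 0.5) and mAP@50~95 (mean over the ten
#' thresholds), plus precision / recall / F1 at a stated confidence
#' threshold and IoU 0.5.  Classes without ground truth are excluded from
#' the means (with a message).  Detections are assumed already filtered and
#' non-max-suppressed.
#'
#' @param dets detections data.frame (`image_id`, `class_id`, `x1..y2`,
#'   `confidence`).
#' @param gts ground-truth data.frame (`image_id`, `class_id`, `x1..y2`).
#' @param n_classes total class count (default 6).
#' @param conf_thr confidence threshold for the P/R/F1 operating point
#'   (default 0.25).
#' @param interpolation AP interpolation rule, see [average_precision()].
#' @return an `eval_result` list: `ap` (n_classes x 10 matrix, NA rows for
#'   absent classes), `map50`, `map50_95`, `precision`, `recall`, `f1`,
#'   `tp`, `fp`, `fn`.
#' @export
map_suite <- function(dets, gts, n_classes = 6L, conf_thr = 0.25,
                      interpolation = "101point") {
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(NA_real_, n_classes, length(thrs),
               dimnames = list(NULL, paste0("iou", thrs)))
  present <- sort(unique(gts$class_id))
  absent <- setdiff(seq_len(n_classes) - 1L, present)
  if (length(absent) > 0L)
    message("classes without ground truth excluded from mAP: ",
            paste(absent, collapse = ", "))
  for (cl in present) {
    gt_count <- sum(gts$class_id == cl)
    for (t in seq_along(thrs)) {
      flags <- class_records(dets, gts, cl, thrs[t])
      ap[cl + 1L, t] <- average_precision(flags, gt_count, interpolation)
    }
  }
  # operating point at conf_thr, IoU 0.5, aggregated over images and classes
  dconf <- dets[dets$confidence >= conf_thr, , drop = FALSE]
  tp <- fp <- fn <- 0L
  for (img in unique(c(dconf$image_id, gts$image_id))) {
    m <- match_detections(dconf[dconf$image_id == img, , drop = FALSE],
                          gts[gts$image_id == img, , drop = FALSE], 0.5)
    tp <- tp + m$tp_count; fp <- fp + m$fp_count; fn <- fn + m$fn_count
  }
  prf <- precision_recall_f1(tp, fp, fn)
  structure(list(ap = ap,
                 map50 = mean(ap[, 1], na.rm = TRUE),
                 map50_95 = mean(rowMeans(ap), na.rm = TRUE),
                 precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]),
                 f1 = unname(prf["f1"]),
                 tp = tp, fp = fp, fn = fn),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mAP@50: %.1f%%   mAP@50~95: %.1f%%\n", 100 * x$map50, 100 * x$map50_95))
  cat(sprintf("P: %.1f%%   R: %.1f%%   F1: %.1f%%   (TP %d / FP %d / FN %d)\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Greedy per-class non-maximum suppression
#'
#' @param dets detections data.frame for one image.
#' @param iou_thr suppression IoU threshold.
#' @return the surviving subset of `dets`.
#' @export
nms <- function(dets, iou_thr = 0.45) {
  keep <- logical(nrow(dets))
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$confidence[idx])]
    boxes <- as.matrix(dets[idx, c("x1", "y1", "x2", "y2"), drop = FALSE])
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep[idx[i]] <- TRUE
      if (i < length(idx)) {
        rest <- (i + 1):length(idx)
        ov <- iou_one_many(boxes[i, ], boxes[rest, , drop = FALSE])
        alive[rest][ov > iou_thr] <- FALSE
      }
    }
  }
  dets[keep, , drop = FALSE]
}
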