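# Detection metrics: IoU, matching, precision/recall/F1, average precision
# and the threshold-sweep mAP suite.

test_that("iou handles identity, disjoint, partial overlap and degenerate boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_warning(z <- iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
  expect_equal(z, 0)
})

test_that("greedy confidence-ordered matching attributes TP/FP/FN correctly", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10, confidence = 0.9)
  m <- match_detections(d1, gt)
  expect_identical(c(m$tp_count, m$fp_count, m$fn_count), c(1L, 0L, 0L))
  # two detections on one gt: the more confident one wins
  d2 <- rbind(d1, data.frame(class_id = 0L, x1 = 1, y1 = 1, x2 = 10, y2 = 10,
                             confidence = 0.95))
  m2 <- match_detections(d2, gt)
  expect_identical(c(m2$tp_count, m2$fp_count, m2$fn_count), c(1L, 1L, 0L))
  expect_true(m2$tp[2] && !m2$tp[1])    # row 2 has higher confidence
  # wrong class cannot match
  d3 <- data.frame(class_id = 1L, x1 = 0, y1 = 0, x2 = 10, y2 = 10, confidence = 0.9)
  m3 <- match_detections(d3, gt)
  expect_identical(c(m3$tp_count, m3$fp_count, m3$fn_count), c(0L, 1L, 1L))
})

test_that("precision/recall/F1 reproduce published pairs and honour conventions", {
  expect_equal(round(f1_score(84.7, 82.2), 1), 83.4)
  expect_equal(round(f1_score(82.5, 79.8), 1), 81.1)
  expect_equal(round(f1_score(88.4, 81), 1), 84.5)
  expect_identical(unname(precision_recall_f1(0, 0, 0)), c(0, 0, 0))
  p <- precision_recall_f1(8, 2, 4)
  expect_equal(unname(p), c(0.8, 8 / 12, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12)))
  # harmonic-mean symmetry
  expect_equal(f1_score(0.3, 0.7), f1_score(0.7, 0.3))
})

test_that("average precision matches the brute-force envelope on the 3-point curve", {
  # 2 gts, detections: conf .9 TP, conf .8 FP, conf .7 TP
  tp <- c(TRUE, FALSE, TRUE)
  # oracle: precision envelope sampled at 0, 0.01, ..., 1
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / 2
  oracle <- mean(vapply(seq(0, 1, 0.01), function(r) {
    i <- which(rec >= r)
    if (!length(i)) 0 else max(prec[min(i):length(prec)])
  }, numeric(1)))
  expect_equal(average_precision(tp, 2), oracle)
  expect_equal(average_precision(logical(0), 2), 0)
  expect_equal(average_precision(rep(TRUE, 5), 5), 1)
  # exact envelope differs from the sampled rule by the discretisation only
  expect_equal(average_precision(tp, 2, "exact"), 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("map_suite separates IoU regimes and is order invariant", {
  gts <- data.frame(image_id = "a", class_id = 0:1,
                    x1 = c(0, 50), y1 = c(0, 50), x2 = c(20, 80), y2 = c(20, 80))
  # jitter boxes so IoU lands in (0.5, 0.55): only the 0.50 threshold passes
  dets <- gts
  dets$x1 <- dets$x1 + c(9.6, 14.4)   # shrinking one side: IoU = 1 - s/w = 0.52
  dets$confidence <- 0.9
  r <- map_suite(dets, gts, n_classes = 2)
  expect_equal(r$map50, 1.0)
  expect_equal(r$map50_95, 0.1)
  # shuffling detections changes nothing
  set.seed(1)
  perm <- sample(nrow(dets))
  r2 <- map_suite(dets[perm, ], gts, n_classes = 2)
  expect_equal(r2$map50_95, r$map50_95)
  expect_equal(r2$f1, r$f1)
  # perfect detector
  perfect <- gts; perfect$confidence <- 1
  rp <- map_suite(perfect, gts, n_classes = 2)
  expect_equal(rp$map50, 1); expect_equal(rp$map50_95, 1)
  expect_message(map_suite(perfect, gts, n_classes = 6), "excluded")
})

test_that("AP is non-increasing in the IoU threshold on random fixtures", {
  for (seed in 1:5) {
    fx <- random_eval_fixture(seed + 100)
    r <- map_suite(fx$dets, fx$gts)
    sweep_means <- colMeans(r$ap, na.rm = TRUE)
    expect_true(all(diff(sweep_means) <= 1e-12))
  }
})

test_that("map_suite agrees with the independent reference evaluator", {
  for (seed in 1:12) {
    fx <- random_eval_fixture(seed)
    r <- map_suite(fx$dets, fx$gts)
    o <- ref_map50_and_sweep(fx$dets, fx$gts)
    expect_lt(abs(r$map50 - o$map50), 1e-4)
    expect_lt(abs(r$map50_95 - o$map50_95), 1e-4)
  }
})

test_that("detections round-trip through JSON lines", {
  d <- data.frame(image_id = c("a", "b"), class_id = c(0L, 3L),
                  x1 = c(1.5, 2), y1 = c(0, 1), x2 = c(9.25, 8), y2 = c(7, 6),
                  confidence = c(0.9, 0.25))
  p <- tempfile(fileext = ".jsonl")
  write_detections_jsonl(d, p)
  expect_identical(length(readLines(p)), 2L)
  back <- read_detections_jsonl(p)
  expect_equal(back, d, ignore_attr = TRUE)
  unlink(p)
})

test_that("nms suppresses same-class overlaps and keeps distinct objects", {
  d <- data.frame(class_id = c(0, 0, 0, 1),
                  x1 = c(0, 1, 50, 0), y1 = c(0, 1, 50, 0),
                  x2 = c(10, 11, 60, 10), y2 = c(10, 11, 60, 10),
                  confidence = c(0.9, 0.8, 0.7, 0.6))
  k <- nms(d, 0.45)
  expect_identical(nrow(k), 3L)
  expect_true(all(c(0.9, 0.7, 0.6) %in% k$confidence))
})
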