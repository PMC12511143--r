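# Training loop mechanics at miniature scale: schedule, assignment, smoke
# training, evaluation determinism and threshold monotonicity.

make_mini_split <- function(n, size = 64, n_objects = 2, seed0 = 100) {
  imgs <- lapply(seq_len(n), function(i) {
    s <- generate_scene(scene_spec(c(size, size), n_objects = n_objects,
                                   seed = seed0 + i))
    s$id <- paste0("im", i); s
  })
  names(imgs) <- vapply(imgs, `[[`, character(1), "id")
  imgs
}

test_that("cosine schedule starts at the initial rate and decays to the floor", {
  expect_equal(cosine_lr(0, 300), 0.01)
  expect_equal(cosine_lr(300, 300), 1e-4)
  expect_equal(cosine_lr(150, 300), (0.01 + 1e-4) / 2)
  mid <- cosine_lr(0:300, 300)
  expect_true(all(diff(mid) < 0))   # monotone decay
})

test_that("target assignment puts the centre cell on the right scale with valid distances", {
  gt <- data.frame(class_id = 2L, x1 = 40, y1 = 40, x2 = 70, y2 = 64)  # 30 px: stride 8
  tg <- giwtnet:::assign_targets(list(gt), 256L)
  expect_gt(nrow(tg[[1]]), 0)
  expect_null(tg[[2]]); expect_null(tg[[3]])
  ctr <- tg[[1]][tg[[1]]$r == floor(52 / 8) & tg[[1]]$c == floor(55 / 8), ]
  expect_identical(nrow(ctr), 1L)
  expect_true(all(tg[[1]][, c("l", "t", "rr", "bb")] >= 0))
  expect_true(all(tg[[1]][, c("l", "t", "rr", "bb")] < 15))
  big <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 180, y2 = 200)  # stride 32
  tg2 <- giwtnet:::assign_targets(list(big), 256L)
  expect_gt(nrow(tg2[[3]]), 0)
  # overlapping boxes: the smaller object keeps contested cells
  both <- rbind(gt, data.frame(class_id = 1L, x1 = 44, y1 = 44, x2 = 66, y2 = 60))
  tg3 <- giwtnet:::assign_targets(list(both), 256L)
  contested <- tg3[[1]][tg3[[1]]$r == 6 & tg3[[1]]$c == 6, ]
  if (nrow(contested) == 1L) expect_identical(contested$cls, 1L)
})

test_that("one epoch of training runs, logs three loss components and steps the weights", {
  imgs <- make_mini_split(4)
  cfg <- train_config(batch_size = 4, epochs = 10, input_size = 64, augment = FALSE,
                      warmup_epochs = 1, early_stop_patience = 10, seed = 3)
  r <- train(cfg, list(train = imgs, val = NULL), spec = network_spec(width = 0.25),
             max_iterations = 2, verbose = FALSE)
  expect_true(all(c("box", "cls", "dfl", "lr") %in% names(r$log)))
  expect_identical(nrow(r$log), 2L)
  expect_true(all(is.finite(as.matrix(r$log[, c("box", "cls", "dfl")]))))
  # losses decrease over a few more steps on the same data
  r2 <- train(cfg, list(train = imgs, val = NULL), spec = network_spec(width = 0.25),
              max_iterations = 8, verbose = FALSE)
  expect_lt(mean(r2$log$cls[7:8]), mean(r2$log$cls[1:2]))
})

test_that("augmented batches keep boxes inside the canvas", {
  imgs <- make_mini_split(4, size = 64)
  cfg <- train_config(batch_size = 4, epochs = 1, input_size = 64, augment = TRUE,
                      mosaic_p = 1, mixup_p = 1, warmup_epochs = 1,
                      early_stop_patience = 1, seed = 9)
  set.seed(9)
  b <- giwtnet:::make_batch(imgs, 1:4, cfg)
  for (g in b$gt) {
    if (is.null(g) || nrow(g) == 0) next
    expect_true(all(g$x1 >= 0 & g$x2 <= 64 & g$y1 >= 0 & g$y2 <= 64))
  }
  expect_identical(dim(b$x), c(64L, 64L, 4L, 3L))
})

test_that("evaluation is deterministic and recall never rises with the threshold", {
  imgs <- make_mini_split(3, size = 64, n_objects = 2)
  spec <- network_spec(width = 0.25)
  model <- build_model(spec, seed = 4)
  e1 <- suppressMessages(evaluate(model, imgs, input_size = 64))
  e2 <- suppressMessages(evaluate(model, imgs, input_size = 64))
  expect_identical(e1$ap, e2$ap)
  expect_identical(e1$f1, e2$f1)
  gts <- ground_truth_table(imgs)
  recalls <- vapply(c(0.001, 0.1, 0.3, 0.6, 0.9), function(thr) {
    dets <- detect_objects(model, imgs, conf_thr = thr, nms_iou = 0.45)
    tp <- fn <- 0L
    for (img in unique(gts$image_id)) {
      m <- match_detections(dets[dets$image_id == img, , drop = FALSE],
                            gts[gts$image_id == img, , drop = FALSE], 0.5)
      tp <- tp + m$tp_count; fn <- fn + m$fn_count
    }
    if (tp + fn == 0) 0 else tp / (tp + fn)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("a non-finite loss aborts with a diagnostic naming the component", {
  imgs <- make_mini_split(2, size = 64)
  cfg <- train_config(batch_size = 2, epochs = 8, input_size = 64, augment = FALSE,
                      warmup_epochs = 0, early_stop_patience = 8, seed = 1)
  model <- build_model(network_spec(width = 0.25), seed = 1)
  params <- giwtnet:::collect_model_params(model)
  params[[1]]$v[1] <- NaN   # corrupt the stem kernel
  batch <- giwtnet:::make_batch(imgs, 1:2, cfg)
  expect_error(giwtnet:::train_step(model, params, batch, cfg, lr = 0.01),
               "non-finite loss: component")
})

test_that("checkpoints round-trip through save and load", {
  imgs <- make_mini_split(2, size = 64)
  cfg <- train_config(batch_size = 2, epochs = 1, input_size = 64, augment = FALSE,
                      warmup_epochs = 1, early_stop_patience = 1, seed = 5)
  ck <- tempfile(fileext = ".rds")
  r <- train(cfg, list(train = imgs, val = imgs), spec = network_spec(width = 0.25),
             max_iterations = 1, checkpoint_path = ck, verbose = FALSE)
  m2 <- load_checkpoint(ck)
  x <- array(runif(64 * 64 * 1 * 3), c(64, 64, 1, 3))
  p1 <- predict(r$model, x)
  p2 <- predict(m2, x)
  expect_equal(p1[[1]], p2[[1]], tolerance = 1e-12)
  unlink(ck)
})
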