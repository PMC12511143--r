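# Synthetic scene generator, VOC XML round-trips, mosaic / mixup and dataset
# layout.

test_that("scene generation is a pure function of the spec and yields valid boxes", {
  sp <- scene_spec(c(128, 128), n_objects = 6, seed = 42)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  if (nrow(a$boxes) > 0) {
    expect_true(all(a$boxes$x2 > a$boxes$x1 & a$boxes$y2 > a$boxes$y1))
    expect_true(all(a$boxes$x1 >= 0 & a$boxes$y1 >= 0 &
                      a$boxes$x2 <= 128 & a$boxes$y2 <= 128))
    expect_true(all(a$boxes$class_id %in% 0:5))
  }
  empty <- generate_scene(scene_spec(c(64, 64), n_objects = 0, seed = 1))
  expect_identical(nrow(empty$boxes), 0L)
  expect_error(scene_spec(class_weights = rep(1, 6)), "sum to 1")
  expect_error(scene_spec(illumination_gain = 0), "positive")
})

test_that("size_mix controls the small/large regime fractions", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    sc <- generate_scene(scene_spec(c(320, 320), n_objects = 20, size_mix = 0.5,
                                    seed = seed))
    size <- pmax(sc$boxes$x2 - sc$boxes$x1, sc$boxes$y2 - sc$boxes$y1)
    # the regimes are 2-6% and 10-25% of the side: cut midway at 8%
    hits <- hits + sum(size < 0.08 * 320)
    total <- total + length(size)
  }
  p <- hits / total
  ci <- 1.96 * sqrt(0.25 / total)
  expect_gt(p, 0.5 - ci - 0.05)
  expect_lt(p, 0.5 + ci + 0.05)
})

test_that("VOC XML writing and reading are exact inverses on integer boxes", {
  sc <- generate_scene(scene_spec(c(96, 96), n_objects = 3, seed = 9))
  sc$boxes[, c("x1", "y1", "x2", "y2")] <- round(sc$boxes[, c("x1", "y1", "x2", "y2")])
  path <- tempfile(fileext = ".xml")
  write_voc_xml(sc, path)
  back <- read_voc_xml(path)
  expect_equal(as.matrix(back[, 1:5]), as.matrix(sc$boxes[, 1:5]),
               ignore_attr = TRUE)
  expect_identical(attr(back, "image_size"), c(96L, 96L))
  # the 0-based internal box (0, 0, 10, 10) is stored 1-based
  one <- sc; one$boxes <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  write_voc_xml(one, path)
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_text(xml2::xml_find_first(doc, ".//xmin")), "1")
  expect_identical(xml2::xml_text(xml2::xml_find_first(doc, ".//xmax")), "10")
  # unknown class names are rejected with the file named
  writeLines(c("<annotation><size><width>9</width><height>9</height><depth>3</depth></size>",
               "<object><name>NotABeetle</name><bndbox><xmin>1</xmin><ymin>1</ymin>",
               "<xmax>5</xmax><ymax>5</ymax></bndbox></object></annotation>"), path)
  expect_error(read_voc_xml(path), "NotABeetle")
})

test_that("mosaic with a fixed centre tiles four images and transforms boxes", {
  imgs <- lapply(1:4, function(i) generate_scene(scene_spec(c(64, 64), n_objects = 2,
                                                            seed = i)))
  mz <- mosaic(imgs, c(128, 128), center = c(0.5, 0.5))
  expect_identical(mz$pixels[1:64, 1:64, ], imgs[[1]]$pixels)
  expect_identical(mz$pixels[1:64, 65:128, ], imgs[[2]]$pixels)
  expect_identical(mz$pixels[65:128, 1:64, ], imgs[[3]]$pixels)
  expect_identical(mz$pixels[65:128, 65:128, ], imgs[[4]]$pixels)
  n_in <- sum(vapply(imgs, function(im) nrow(im$boxes), integer(1)))
  expect_identical(nrow(mz$boxes), n_in)  # untouched quadrants keep every box
  expect_true(all(mz$boxes$x1 >= 0 & mz$boxes$x2 <= 128 &
                    mz$boxes$y1 >= 0 & mz$boxes$y2 <= 128))
  # an off-centre split clips boxes exactly to their quadrant
  mz2 <- mosaic(imgs, c(128, 128), center = c(0.4, 0.6))
  expect_true(all(mz2$boxes$x1 >= 0 & mz2$boxes$x2 <= 128))
})

test_that("mixup blends pixels and unions weighted boxes", {
  a <- generate_scene(scene_spec(c(64, 64), n_objects = 2, seed = 1))
  b <- generate_scene(scene_spec(c(64, 64), n_objects = 3, seed = 2))
  m <- mixup(a, b, 0.5)
  expect_equal(m$pixels, 0.5 * a$pixels + 0.5 * b$pixels)
  expect_identical(nrow(m$boxes), nrow(a$boxes) + nrow(b$boxes))
  expect_equal(sort(unique(m$boxes$weight)), 0.5)
  e1 <- mixup(a, b, 1)
  expect_equal(e1$pixels, a$pixels)
  black <- list(pixels = array(0, c(64, 64, 3)),
                boxes = a$boxes[0, ])
  white <- list(pixels = array(255, c(64, 64, 3)), boxes = a$boxes[0, ])
  expect_true(all(mixup(black, white, 0.5)$pixels == 127.5))
  small <- list(pixels = array(0, c(32, 32, 3)), boxes = a$boxes[0, ])
  expect_error(mixup(a, small), "identical image sizes")
})

test_that("make_dataset writes a complete, disjoint, class-balanced layout", {
  dir <- file.path(tempdir(), "giwt_ds_test")
  unlink(dir, recursive = TRUE)
  make_dataset(dir, n_train = 12, n_val = 3, n_test = 3,
               template = scene_spec(c(96, 96), n_objects = 4), seed = 5)
  expect_length(list.files(file.path(dir, "images")), 18L)
  expect_length(list.files(file.path(dir, "annotations")), 18L)
  manifests <- lapply(c("train", "val", "test"),
                      function(s) readLines(file.path(dir, paste0(s, ".txt"))))
  expect_identical(lengths(manifests), c(12L, 3L, 3L))
  all_ids <- unlist(manifests)
  expect_identical(anyDuplicated(all_ids), 0L)
  # determinism of the whole corpus
  dir2 <- file.path(tempdir(), "giwt_ds_test2")
  unlink(dir2, recursive = TRUE)
  make_dataset(dir2, n_train = 12, n_val = 3, n_test = 3,
               template = scene_spec(c(96, 96), n_objects = 4), seed = 5)
  f <- "img_0001.png"
  expect_identical(readBin(file.path(dir, "images", f), "raw", 1e6),
                   readBin(file.path(dir2, "images", f), "raw", 1e6))
  # every annotation ingests into the metrics machinery
  tr <- load_split(dir, "train")
  gts <- ground_truth_table(tr)
  expect_true(nrow(gts) > 0)
  expect_true(all(gts$class_id %in% 0:5))
  # class frequencies within the multinomial 95% envelope of equal weights
  tab <- table(factor(gts$class_id, levels = 0:5))
  n <- sum(tab)
  expect_true(all(abs(tab / n - 1 / 6) < 1.96 * sqrt((1 / 6) * (5 / 6) / n) + 0.05))
  unlink(dir, recursive = TRUE); unlink(dir2, recursive = TRUE)
})

test_that("an oracle detector scores a perfect mAP on a generated split", {
  imgs <- lapply(1:4, function(i) {
    s <- generate_scene(scene_spec(c(96, 96), n_objects = 3, seed = i))
    s$id <- paste0("im", i); s
  })
  names(imgs) <- vapply(imgs, `[[`, character(1), "id")
  gts <- ground_truth_table(imgs)
  oracle <- gts
  oracle$confidence <- 0.99
  r <- suppressMessages(map_suite(oracle, gts))
  expect_equal(r$map50, 1)
  expect_equal(r$map50_95, 1)
})
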