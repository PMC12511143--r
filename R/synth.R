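# Synthetic annotated bark-beetle scenes.  The generator emulates the
# statistical structure of trap imagery: six visually similar classes, a
# strongly bimodal body-size distribution (small- vs large-pest regimes),
# class-dependent but confusable body hue / texture, and varying
# illumination.  It is a statistics emulator, not a beetle renderer.

#' Class names of the six pest categories
#' @return character vector of length 6 (class ids 0-5 in this order).
#' @export
pest_classes <- function() {
  c("Boerner", "Leconte", "Linnaeus", "Acuminatus", "Armandi", "Coleoptera")
}

# Base visual prototypes: hue (RGB), texture spatial frequency (cycles per
# body length) and texture contrast per class.  Confusability interpolates
# each prototype toward the pooled mean.
.class_prototypes <- function() {
  list(rgb = matrix(c(0.45, 0.28, 0.12,   # Boerner: chestnut
                      0.32, 0.22, 0.10,   # Leconte: dark brown
                      0.52, 0.38, 0.18,   # Linnaeus: light brown
                      0.25, 0.18, 0.12,   # Acuminatus: umber
                      0.38, 0.30, 0.20,   # Armandi: grey-brown
                      0.20, 0.14, 0.08),  # Coleoptera: near-black
                    nrow = 6, byrow = TRUE),
       freq = c(3, 5, 2, 6, 4, 7),
       contrast = c(0.12, 0.18, 0.10, 0.20, 0.15, 0.22))
}

#' Scene specification for the synthetic generator
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_objects number of objects to place (placement failures after
#'   bounded retries reduce the count, with a message).
#' @param class_weights six non-negative weights summing to 1.
#' @param size_mix fraction of objects drawn from the small-size regime
#'   (body length 2-6% of the image side; large regime 10-25%).
#' @param illumination_gain multiplicative brightness factor (> 0).
#' @param texture_confusability in `[0, 1]`: 0 keeps class prototypes fully
#'   distinct, 1 collapses them to a common appearance.
#' @param seed RNG seed making the scene a pure function of the spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(320L, 320L), n_objects = 8L,
                       class_weights = rep(1 / 6, 6), size_mix = 0.5,
                       illumination_gain = 1.0, texture_confusability = 0.5,
                       seed = 0L) {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  if (abs(sum(class_weights) - 1) > 1e-9) stop("class_weights must sum to 1", call. = FALSE)
  if (any(class_weights < 0)) stop("class_weights must be non-negative", call. = FALSE)
  if (illumination_gain <= 0) stop("illumination_gain must be positive", call. = FALSE)
  stopifnot(size_mix >= 0, size_mix <= 1,
            texture_confusability >= 0, texture_confusability <= 1)
  structure(list(image_size = as.integer(image_size), n_objects = as.integer(n_objects),
                 class_weights = class_weights, size_mix = size_mix,
                 illumination_gain = illumination_gain,
                 texture_confusability = texture_confusability,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate one annotated synthetic scene
#'
#' Renders a textured background and `n_objects` oriented elliptical bodies
#' with class-dependent colour and body texture; bounding boxes are the
#' tight axis-aligned hulls of the rotated ellipses.  Deterministic under
#' `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list of class `annotated_image`: `pixels` (`(H, W, 3)` in
#'   `[0, 255]`), `boxes` (data.frame `class_id`, `x1..y2` 0-based pixels),
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    side <- min(H, W)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    # background: warm grey base + low-frequency gratings + speckle
    base <- 0.62 + 0.05 * sin(2 * pi * (xx * runif(1, 0.5, 2) + yy * runif(1, 0.5, 2)) / side) +
      0.04 * sin(2 * pi * (xx * runif(1, 2, 5) - yy * runif(1, 2, 5)) / side + runif(1, 0, 2 * pi))
    img <- array(0, dim = c(H, W, 3))
    tint <- c(1.0, 0.96, 0.88)
    for (ch in 1:3) img[, , ch] <- base * tint[ch] + matrix(rnorm(H * W, 0, 0.02), H, W)
    proto <- .class_prototypes()
    conf <- spec$texture_confusability
    mix <- function(v) (1 - conf) * v + conf * mean(v)
    rgb_mixed <- apply(proto$rgb, 2, function(col) (1 - conf) * col + conf * mean(col))
    freq_mixed <- mix(proto$freq)
    contrast_mixed <- mix(proto$contrast)
    boxes <- list()
    placed <- matrix(numeric(0), 0, 4)
    n_done <- 0L
    for (obj in seq_len(spec$n_objects)) {
      cls <- sample.int(6L, 1L, prob = spec$class_weights) - 1L
      small <- runif(1) < spec$size_mix
      len_frac <- if (small) runif(1, 0.02, 0.06) else runif(1, 0.10, 0.25)
      a <- len_frac * side / 2                      # semi-major axis
      b <- a * runif(1, 0.45, 0.75)                 # beetles are elongated
      theta <- runif(1, 0, pi)
      hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
      hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
      ok <- FALSE
      for (try in 1:20) {
        cx <- runif(1, hw + 1, W - hw - 1)
        cy <- runif(1, hh + 1, H - hh - 1)
        cand <- c(cx - hw, cy - hh, cx + hw, cy + hh)
        if (nrow(placed) == 0L || all(iou_one_many(cand, placed) < 0.25)) { ok <- TRUE; break }
      }
      if (!ok) next
      placed <- rbind(placed, cand)
      # render the rotated ellipse within its bounding window
      x0 <- max(1L, floor(cx - hw)); x1 <- min(W, ceiling(cx + hw))
      y0 <- max(1L, floor(cy - hh)); y1 <- min(H, ceiling(cy + hh))
      wy <- yy[y0:y1, x0:x1] - cy
      wx <- xx[y0:y1, x0:x1] - cx
      u <- (wx * cos(theta) + wy * sin(theta)) / a
      v <- (-wx * sin(theta) + wy * cos(theta)) / b
      r2 <- u^2 + v^2
      mask <- r2 <= 1
      edge <- pmin(1, pmax(0, (1 - r2) * 6))       # soft rim
      tex <- 1 + contrast_mixed[cls + 1L] *
        sin(2 * pi * freq_mixed[cls + 1L] * u + runif(1, 0, 2 * pi)) +
        matrix(rnorm(length(u), 0, 0.05), nrow(u))
      shade <- 1 - 0.35 * r2                        # darker toward the rim
      for (ch in 1:3) {
        patch <- img[y0:y1, x0:x1, ch]
        body <- rgb_mixed[cls + 1L, ch] * tex * shade
        patch[mask] <- patch[mask] * (1 - edge[mask]) + body[mask] * edge[mask]
        img[y0:y1, x0:x1, ch] <- patch
      }
      n_done <- n_done + 1L
      boxes[[n_done]] <- data.frame(class_id = cls,
                                    x1 = cx - hw, y1 = cy - hh,
                                    x2 = cx + hw, y2 = cy + hh)
    }
    if (n_done < spec$n_objects)
      message(sprintf("placed %d of %d objects (overlap limit)", n_done, spec$n_objects))
    img <- img * spec$illumination_gain
    img <- pmin(pmax(img, 0), 1) * 255
    boxes <- if (n_done > 0L) do.call(rbind, boxes)
             else data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                             x2 = numeric(0), y2 = numeric(0))
    structure(list(pixels = img, boxes = boxes, spec = spec), class = "annotated_image")
  })
}

#' Write an annotation in Pascal-VOC XML dialect
#'
#' Coordinates are stored 1-based inclusive (`xmin = x1 + 1` for a 0-based
#' internal box); object names are the class strings of [pest_classes()].
#'
#' @param img an `annotated_image` (or any list with `pixels` and `boxes`).
#' @param path output XML file path.
#' @param image_filename the image file name recorded in the annotation.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(img, path, image_filename = "image.png") {
  d <- dim(img$pixels)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", image_filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(d[2]))
  xml2::xml_add_child(size, "height", as.character(d[1]))
  xml2::xml_add_child(size, "depth", "3")
  cls <- pest_classes()
  if (nrow(img$boxes) > 0) for (i in seq_len(nrow(img$boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", cls[img$boxes$class_id[i] + 1L])
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(round(img$boxes$x1[i]) + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(round(img$boxes$y1[i]) + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(round(img$boxes$x2[i])))
    xml2::xml_add_child(bb, "ymax", as.character(round(img$boxes$y2[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Pascal-VOC XML annotation
#'
#' Exact inverse of [write_voc_xml()] on integer boxes: the stored 1-based
#' inclusive coordinates are converted back to 0-based corners.
#'
#' @param path XML file path.
#' @return data.frame with `class_id`, `x1`, `y1`, `x2`, `y2` and attribute
#'   `"image_size"` `(H, W)`.
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("malformed XML in '%s': %s", path,
                                                   conditionMessage(e)), call. = FALSE))
  cls <- pest_classes()
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, tag) as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  rows <- lapply(objs, function(ob) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "name"))
    id <- match(nm, cls)
    if (is.na(id))
      stop(sprintf("unknown class name '%s' in '%s' (element <object>)", nm, path), call. = FALSE)
    data.frame(class_id = id - 1L,
               x1 = get_num(ob, ".//xmin") - 1, y1 = get_num(ob, ".//ymin") - 1,
               x2 = get_num(ob, ".//xmax"), y2 = get_num(ob, ".//ymax"))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                         x2 = numeric(0), y2 = numeric(0))
  sz <- xml2::xml_find_first(doc, ".//size")
  attr(out, "image_size") <- c(as.integer(xml2::xml_text(xml2::xml_find_first(sz, "height"))),
                               as.integer(xml2::xml_text(xml2::xml_find_first(sz, "width"))))
  out
}

# Nearest-neighbour resize of an (H, W, 3) image.
resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  ri <- pmin(d[1], pmax(1L, round((seq_len(out_h) - 0.5) * d[1] / out_h + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(out_w) - 0.5) * d[2] / out_w + 0.5)))
  img[ri, ci, , drop = FALSE]
}

#' Mosaic augmentation of four annotated images
#'
#' A random centre point splits the output canvas into four quadrants; each
#' input is rescaled into one quadrant.  Boxes are transformed and clipped;
#' a box is dropped when its clipped area falls below 10% of its transformed
#' area.
#'
#' @param images list of 4 `annotated_image` objects.
#' @param out_size output `(H, W)`.
#' @param seed RNG seed; also accepts `center` to fix the split point.
#' @param center optional `(cy, cx)` fraction pair in (0,1) overriding the
#'   random centre.
#' @return an `annotated_image`.
#' @export
mosaic <- function(images, out_size = c(320L, 320L), seed = 0L, center = NULL) {
  stopifnot(length(images) == 4L)
  with_seed(seed, {
    H <- out_size[1]; W <- out_size[2]
    if (is.null(center)) center <- c(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7))
    cy <- round(H * center[1]); cx <- round(W * center[2])
    quads <- list(c(1, 1, cy, cx), c(1, cx + 1, cy, W),
                  c(cy + 1, 1, H, cx), c(cy + 1, cx + 1, H, W))
    canvas <- array(0, dim = c(H, W, 3))
    boxes <- list()
    for (q in 1:4) {
      y0 <- quads[[q]][1]; x0 <- quads[[q]][2]; y1 <- quads[[q]][3]; x1 <- quads[[q]][4]
      qh <- y1 - y0 + 1L; qw <- x1 - x0 + 1L
      if (qh < 1 || qw < 1) next
      src <- images[[q]]
      sd <- dim(src$pixels)
      canvas[y0:y1, x0:x1, ] <- resize_nearest(src$pixels, qh, qw)
      if (nrow(src$boxes) == 0L) next
      sy <- qh / sd[1]; sx <- qw / sd[2]
      b <- src$boxes
      tx1 <- b$x1 * sx + (x0 - 1L); tx2 <- b$x2 * sx + (x0 - 1L)
      ty1 <- b$y1 * sy + (y0 - 1L); ty2 <- b$y2 * sy + (y0 - 1L)
      area_t <- (tx2 - tx1) * (ty2 - ty1)
      cx1 <- pmax(tx1, x0 - 1L); cx2 <- pmin(tx2, x1)
      cy1 <- pmax(ty1, y0 - 1L); cy2 <- pmin(ty2, y1)
      area_c <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0)
      keep <- area_c >= 0.1 * area_t & area_c > 0
      if (any(keep)) boxes[[length(boxes) + 1L]] <-
        data.frame(class_id = b$class_id[keep], x1 = cx1[keep], y1 = cy1[keep],
                   x2 = cx2[keep], y2 = cy2[keep])
    }
    boxes <- if (length(boxes)) do.call(rbind, boxes)
             else data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                             x2 = numeric(0), y2 = numeric(0))
    structure(list(pixels = canvas, boxes = boxes, spec = NULL), class = "annotated_image")
  })
}

#' Mixup augmentation of two annotated images
#'
#' Convex pixel blend `lam * a + (1 - lam) * b`; the box list is the union
#' of both inputs' boxes, each carrying its source mixing weight in a
#' `weight` column.
#'
#' @param a,b `annotated_image` objects of equal size.
#' @param lam mixing coefficient in `(0, 1)`.
#' @return an `annotated_image` with weighted boxes.
#' @export
mixup <- function(a, b, lam = 0.5) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("mixup inputs must have identical image sizes", call. = FALSE)
  stopifnot(lam >= 0, lam <= 1)
  px <- lam * a$pixels + (1 - lam) * b$pixels
  ab <- a$boxes; bb <- b$boxes
  if (nrow(ab)) ab$weight <- lam
  if (nrow(bb)) bb$weight <- 1 - lam
  boxes <- rbind(ab, bb)
  structure(list(pixels = px, boxes = boxes, spec = NULL), class = "annotated_image")
}

#' Generate a dataset directory of annotated synthetic scenes
#'
#' Writes `images/*.png`, `annotations/*.xml` and the split manifests
#' `train.txt` / `val.txt` / `test.txt` (one image id per line).  The
#' default counts keep the published 1693:245:245 split proportions at desk
#' scale.  Per-image variation (object count, illumination, seed) derives
#' deterministically from `seed`.
#'
#' @param dir output directory (created).
#' @param n_train,n_val,n_test split sizes (defaults 64 / 8 / 8).
#' @param template a [scene_spec()] used as the per-image template.
#' @param seed dataset-level RNG seed.
#' @return `dir`, invisibly.
#' @export
make_dataset <- function(dir, n_train = 64L, n_val = 8L, n_test = 8L,
                         template = scene_spec(), seed = 0L) {
  ok <- dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "images")))
    stop(sprintf("cannot create dataset directory '%s'", dir), call. = FALSE)
  counts <- c(train = n_train, val = n_val, test = n_test)
  idx <- 0L
  with_seed(seed, {
    for (split in names(counts)) {
      ids <- character(0)
      for (i in seq_len(counts[[split]])) {
        idx <- idx + 1L
        id <- sprintf("img_%04d", idx)
        sp <- scene_spec(image_size = template$image_size,
                         n_objects = max(1L, stats::rpois(1, template$n_objects)),
                         class_weights = template$class_weights,
                         size_mix = template$size_mix,
                         illumination_gain = template$illumination_gain * runif(1, 0.6, 1.4),
                         texture_confusability = template$texture_confusability,
                         seed = sample.int(.Machine$integer.max, 1L))
        scn <- generate_scene(sp)
        png::writePNG(scn$pixels / 255, file.path(dir, "images", paste0(id, ".png")))
        write_voc_xml(scn, file.path(dir, "annotations", paste0(id, ".xml")),
                      paste0(id, ".png"))
        ids <- c(ids, id)
      }
      writeLines(ids, file.path(dir, paste0(split, ".txt")))
    }
  })
  invisible(dir)
}

#' Load a dataset split
#'
#' @param dir dataset directory from [make_dataset()].
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list of `annotated_image` objects (pixels in `[0, 255]`), named
#'   by image id.
#' @export
load_split <- function(dir, split = "train") {
  ids <- readLines(file.path(dir, paste0(split, ".txt")))
  out <- lapply(ids, function(id) {
    px <- png::readPNG(file.path(dir, "images", paste0(id, ".png"))) * 255
    boxes <- read_voc_xml(file.path(dir, "annotations", paste0(id, ".xml")))
    structure(list(pixels = px, boxes = boxes, id = id), class = "annotated_image")
  })
  names(out) <- ids
  out
}
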