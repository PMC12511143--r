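# Literal, unoptimised reference implementations used as independent oracles.
# They share no code with the package's forward paths: plain nested loops and
# direct formula evaluation only.

ref_conv_naive <- function(x, w, stride = 1L, pad = NULL) {
  d <- dim(x)  # (H, W, N, C)
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  y <- array(0, dim = c(Ho, Wo, d[3], cout))
  for (n in seq_len(d[3])) for (co in seq_len(cout)) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        h <- (ho - 1L) * stride - pad + ki
        ww <- (wo - 1L) * stride - pad + kj
        if (h >= 1 && h <= d[1] && ww >= 1 && ww <= d[2])
          acc <- acc + x[h, ww, n, ci] * w[ki, kj, ci, co]
      }
      y[ho, wo, n, co] <- acc
    }
  }
  y
}

ref_dwconv_naive <- function(x, w, stride = 1L, pad = NULL) {
  d <- dim(x)
  k <- dim(w)[1]
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  y <- array(0, dim = c(Ho, Wo, d[3], d[4]))
  for (cc in seq_len(d[4])) for (n in seq_len(d[3])) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        h <- (ho - 1L) * stride - pad + ki
        ww <- (wo - 1L) * stride - pad + kj
        if (h >= 1 && h <= d[1] && ww >= 1 && ww <= d[2])
          acc <- acc + x[h, ww, n, cc] * w[ki, kj, cc]
      }
      y[ho, wo, n, cc] <- acc
    }
  }
  y
}

ref_maxpool_naive <- function(x, k, stride = 1L, pad = NULL) {
  d <- dim(x)
  if (is.null(pad)) pad <- k %/% 2L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  y <- array(-Inf, dim = c(Ho, Wo, d[3], d[4]))
  for (cc in seq_len(d[4])) for (n in seq_len(d[3])) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      best <- -Inf
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        h <- (ho - 1L) * stride - pad + ki
        ww <- (wo - 1L) * stride - pad + kj
        if (h >= 1 && h <= d[1] && ww >= 1 && ww <= d[2])
          best <- max(best, x[h, ww, n, cc])
      }
      y[ho, wo, n, cc] <- best
    }
  }
  y
}

ref_bn_eval <- function(x, gamma, beta, eps = 1e-5) {
  # fresh layers carry running mean 0 / var 1
  d <- dim(x)
  y <- x
  for (cc in seq_len(d[4])) y[, , , cc] <- gamma[cc] * x[, , , cc] / sqrt(1 + eps) + beta[cc]
  y
}

ref_silu <- function(x) x / (1 + exp(-x))

ref_conv_block <- function(x, layer, stride = 1L) {
  y <- ref_conv_naive(x, layer$params$w$v, layer$stride, layer$pad)
  y <- ref_bn_eval(y, layer$params$gamma$v, layer$params$beta$v)
  if (layer$act) ref_silu(y) else y
}

ref_inception <- function(x, layer) {
  b1 <- ref_conv_block(x, layer$children$b1)
  b2 <- ref_conv_block(ref_conv_block(x, layer$children$b2$children$m1),
                       layer$children$b2$children$m2)
  b3 <- ref_conv_block(ref_conv_block(ref_conv_block(x, layer$children$b3$children$m1),
                                      layer$children$b3$children$m2),
                       layer$children$b3$children$m3)
  b4 <- ref_conv_block(ref_maxpool_naive(x, 3L, 1L, 1L), layer$children$b4)
  d <- dim(b1)
  y <- array(0, dim = c(d[1], d[2], d[3], 4L * d[4]))
  y[, , , seq_len(d[4])] <- b1
  y[, , , d[4] + seq_len(d[4])] <- b2
  y[, , , 2L * d[4] + seq_len(d[4])] <- b3
  y[, , , 3L * d[4] + seq_len(d[4])] <- b4
  y
}

ref_giconv <- function(x, layer) {
  core <- ref_conv_block(x, layer$children$primary)
  inc <- ref_inception(core, layer$children$inception)
  d <- dim(core)
  y <- array(0, dim = c(d[1], d[2], d[3], d[4] + dim(inc)[4]))
  y[, , , seq_len(d[4])] <- core
  y[, , , d[4] + seq_len(dim(inc)[4])] <- inc
  y
}

# Literal 2x2-block Haar analysis / synthesis (even sizes).
ref_haar_dwt <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  LL <- LH <- HL <- HH <- array(0, dim = c(h2, w2, d[3], d[4]))
  for (cc in seq_len(d[4])) for (n in seq_len(d[3])) {
    for (i in seq_len(h2)) for (j in seq_len(w2)) {
      a <- x[2 * i - 1, 2 * j - 1, n, cc]; b <- x[2 * i - 1, 2 * j, n, cc]
      cl <- x[2 * i, 2 * j - 1, n, cc]; dd <- x[2 * i, 2 * j, n, cc]
      LL[i, j, n, cc] <- (a + b + cl + dd) / 2
      LH[i, j, n, cc] <- (a - b + cl - dd) / 2
      HL[i, j, n, cc] <- (a + b - cl - dd) / 2
      HH[i, j, n, cc] <- (a - b - cl + dd) / 2
    }
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

ref_haar_idwt <- function(b) {
  d <- dim(b$LL)
  y <- array(0, dim = c(2L * d[1], 2L * d[2], d[3], d[4]))
  for (cc in seq_len(d[4])) for (n in seq_len(d[3])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      L <- b$LL[i, j, n, cc]; lh <- b$LH[i, j, n, cc]
      hl <- b$HL[i, j, n, cc]; hh <- b$HH[i, j, n, cc]
      y[2 * i - 1, 2 * j - 1, n, cc] <- (L + lh + hl + hh) / 2
      y[2 * i - 1, 2 * j, n, cc] <- (L - lh + hl - hh) / 2
      y[2 * i, 2 * j - 1, n, cc] <- (L + lh - hl - hh) / 2
      y[2 * i, 2 * j, n, cc] <- (L - lh - hl + hh) / 2
    }
  }
  y
}

# Literal WTConv cascade with explicit per-level loops (even input sizes,
# so no padding branch is involved).
ref_wtconv <- function(x, layer) {
  cfg <- layer$cfg
  C <- cfg$channels; L <- cfg$num_levels; k <- cfg$kernel_size
  cur <- x
  lls <- list(); highs <- list()
  for (i in seq_len(L)) {
    b <- ref_haar_dwt(cur)
    d <- dim(b$LL)
    stacked <- array(0, dim = c(d[1], d[2], d[3], 4L * C))
    stacked[, , , seq_len(C)] <- b$LL
    stacked[, , , C + seq_len(C)] <- b$LH
    stacked[, , , 2L * C + seq_len(C)] <- b$HL
    stacked[, , , 3L * C + seq_len(C)] <- b$HH
    conv <- ref_dwconv_naive(stacked, layer$params[[paste0("lvl", i, "_w")]]$v, 1L, k %/% 2L)
    sc <- layer$params[[paste0("lvl", i, "_s")]]$v
    for (cc in seq_len(4L * C)) conv[, , , cc] <- conv[, , , cc] * sc[cc]
    lls[[i]] <- conv[, , , seq_len(C), drop = FALSE]
    highs[[i]] <- conv[, , , C + seq_len(3L * C), drop = FALSE]
    cur <- b$LL
  }
  rec <- NULL
  for (i in rev(seq_len(L))) {
    ll <- if (is.null(rec)) lls[[i]] else lls[[i]] + rec
    rec <- ref_haar_idwt(list(LL = ll,
                              LH = highs[[i]][, , , seq_len(C), drop = FALSE],
                              HL = highs[[i]][, , , C + seq_len(C), drop = FALSE],
                              HH = highs[[i]][, , , 2L * C + seq_len(C), drop = FALSE]))
  }
  if (cfg$include_base_path) {
    base <- ref_dwconv_naive(x, layer$params$base_w$v, 1L, k %/% 2L)
    bs <- layer$params$base_s$v
    for (cc in seq_len(C)) base[, , , cc] <- base[, , , cc] * bs[cc]
    rec <- rec + base
  }
  rec
}

# Independent evaluator: same metric definitions, different algorithmic path
# (pairwise IoU by formula, exhaustive greedy matching, AP by scanning all
# curve points at each of the 101 recall samples).
ref_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

ref_map50_and_sweep <- function(dets, gts, n_classes = 6L) {
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(NA_real_, n_classes, length(thrs))
  for (cl in sort(unique(gts$class_id))) {
    ngt <- sum(gts$class_id == cl)
    d <- dets[dets$class_id == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    for (ti in seq_along(thrs)) {
      used <- list()
      tp <- logical(nrow(d))
      if (nrow(d) > 0) for (i in seq_len(nrow(d))) {
        g <- gts[gts$class_id == cl & gts$image_id == d$image_id[i], , drop = FALSE]
        best <- 0; bestj <- NA
        if (nrow(g) > 0) for (j in seq_len(nrow(g))) {
          key <- paste(d$image_id[i], rownames(g)[j])
          if (!is.null(used[[key]])) next
          ov <- ref_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                        as.numeric(g[j, c("x1", "y1", "x2", "y2")]))
          if (ov > best) { best <- ov; bestj <- j }
        }
        if (!is.na(bestj) && best >= thrs[ti]) {
          tp[i] <- TRUE
          used[[paste(d$image_id[i], rownames(g)[bestj])]] <- TRUE
        }
      }
      if (length(tp) == 0L) { ap[cl + 1L, ti] <- 0; next }
      rec <- cumsum(tp) / ngt
      prec <- cumsum(tp) / seq_along(tp)
      vals <- vapply(seq(0, 1, by = 0.01), function(r) {
        cand <- prec[rec >= r]
        if (length(cand) == 0L) 0 else {
          # precision envelope: best precision among all points at recall >= r
          best <- 0
          for (idx in which(rec >= r)) {
            e <- max(prec[idx:length(prec)])
            best <- max(best, e)
          }
          best
        }
      }, numeric(1))
      ap[cl + 1L, ti] <- mean(vals)
    }
  }
  list(map50 = mean(ap[, 1], na.rm = TRUE),
       map50_95 = mean(rowMeans(ap), na.rm = TRUE),
       ap = ap)
}

# A random detection-vs-ground-truth fixture on a 100x100 canvas.
random_eval_fixture <- function(seed) {
  set.seed(seed)
  n_img <- sample(1:3, 1)
  gts <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    n <- sample(1:5, 1)
    x1 <- runif(n, 0, 70); y1 <- runif(n, 0, 70)
    data.frame(image_id = paste0("im", im), class_id = sample(0:5, n, replace = TRUE),
               x1 = x1, y1 = y1, x2 = x1 + runif(n, 8, 30), y2 = y1 + runif(n, 8, 30))
  }))
  dets <- do.call(rbind, lapply(seq_len(nrow(gts)), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    jx <- runif(k, -6, 6); jy <- runif(k, -6, 6)
    data.frame(image_id = gts$image_id[i],
               class_id = ifelse(runif(k) < 0.8, gts$class_id[i], sample(0:5, k, replace = TRUE)),
               x1 = gts$x1[i] + jx, y1 = gts$y1[i] + jy,
               x2 = gts$x2[i] + jx * 0.5, y2 = gts$y2[i] + jy * 0.5,
               confidence = runif(k, 0.05, 0.99))
  }))
  extra <- data.frame(image_id = sample(gts$image_id, 2, replace = TRUE),
                      class_id = sample(0:5, 2, replace = TRUE),
                      x1 = runif(2, 0, 70), y1 = runif(2, 0, 70),
                      x2 = NA, y2 = NA, confidence = runif(2, 0.05, 0.99))
  extra$x2 <- extra$x1 + runif(2, 8, 30); extra$y2 <- extra$y1 + runif(2, 8, 30)
  dets <- rbind(dets, extra)
  rownames(gts) <- NULL
  list(dets = dets, gts = gts)
}

# Finite-difference gradient check for autograd ops.
fd_check <- function(make_loss, param, leaves, h = 1e-6, n_probe = 8) {
  for (p in leaves) p$grad <- NULL
  l0 <- make_loss()
  giwtnet:::tn_backward(l0)
  g <- param$grad
  for (p in leaves) p$grad <- NULL
  idx <- sample(length(param$v), min(n_probe, length(param$v)))
  num <- vapply(idx, function(i) {
    old <- param$v[i]
    param$v[i] <- old + h; lp <- make_loss()$v
    param$v[i] <- old - h; lm <- make_loss()$v
    param$v[i] <- old
    (lp - lm) / (2 * h)
  }, numeric(1))
  max(abs(num - g[idx]) / pmax(1e-4, abs(num)))
}
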