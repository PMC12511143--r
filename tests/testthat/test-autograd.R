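# Finite-difference validation of the reverse-mode engine: every primitive
# that carries learnable parameters or feeds the loss must reproduce its
# numerical gradient.

test_that("core op gradients match finite differences", {
  set.seed(7)
  tn_param <- giwtnet:::tn_param
  x <- tn_param(array(rnorm(6 * 6 * 2 * 4), c(6, 6, 2, 4)))
  w <- tn_param(array(rnorm(3 * 3 * 4 * 5) * 0.3, c(3, 3, 4, 5)))
  dw <- tn_param(array(rnorm(3 * 3 * 4) * 0.3, c(3, 3, 4)))
  g <- tn_param(rnorm(4)); b <- tn_param(rnorm(4))
  st <- new.env(); st$running_mean <- rep(0, 4); st$running_var <- rep(1, 4)
  leaves <- list(x, w, dw, g, b)
  with(as.list(asNamespace("giwtnet")), {
    expect_lt(fd_check(function() op_sum(op_silu(op_conv2d(x, w, 2L, 1L))), x, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_silu(op_conv2d(x, w, 2L, 1L))), w, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_dwconv2d(x, dw, 1L, 1L))), x, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_dwconv2d(x, dw, 1L, 1L))), dw, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_batchnorm(x, g, b, st, TRUE))), x, leaves), 1e-2)
    expect_lt(fd_check(function() op_sum(op_square(op_batchnorm(x, g, b, st, TRUE))), g, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_batchnorm(x, g, b, st, TRUE))), b, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_maxpool(x, 3L, 2L, 1L))), x, leaves, h = 1e-5), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_haar_dwt(x))), x, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_haar_idwt(x))), x, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_upsample2(x))), x, leaves), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(op_pad_edge(x, 1L, 1L))), x, leaves), 1e-5)
  })
})

test_that("loss-primitive gradients match finite differences", {
  set.seed(11)
  tn_param <- giwtnet:::tn_param
  with(as.list(asNamespace("giwtnet")), {
    xm <- tn_param(matrix(rnorm(12), 3, 4))
    tgt <- matrix(rbinom(12, 1, 0.5), 3, 4)
    expect_lt(fd_check(function() op_bce_sum(xm, tgt, 0.7), xm, list(xm)), 1e-5)
    lg <- tn_param(matrix(rnorm(4 * 16), 4, 16))
    tt <- runif(4, 0, 14.9)
    expect_lt(fd_check(function() op_dfl_sum(lg, tt, c(1, 2, 0.5, 1)), lg, list(lg)), 1e-4)
    sm <- tn_param(matrix(rnorm(12), 3, 4))
    expect_lt(fd_check(function() op_sum(op_square(op_softmax_rows(sm))), sm, list(sm)), 1e-4)
    # CIoU value against a direct formula (alpha is detached inside the op,
    # so its gradient is checked through an undetached composite below)
    p <- tn_param(matrix(c(1, 1, 6, 7, 2, 3, 9, 8), 2, 4))
    gx1 <- c(1.5, 2.5); gy1 <- c(0.5, 2.0); gx2 <- c(6.5, 8.0); gy2 <- c(7.5, 9.0)
    lv <- tn_value(ciou_loss(op_col(p, 1L), op_col(p, 2L), op_col(p, 3L), op_col(p, 4L),
                             gx1, gy1, gx2, gy2))
    direct <- vapply(1:2, function(i) {
      b <- p$v[i, ]
      iw <- max(0, min(b[3], gx2[i]) - max(b[1], gx1[i]))
      ih <- max(0, min(b[4], gy2[i]) - max(b[2], gy1[i]))
      inter <- iw * ih
      un <- (b[3] - b[1]) * (b[4] - b[2]) + (gx2[i] - gx1[i]) * (gy2[i] - gy1[i]) - inter
      iouv <- inter / (un + 1e-9)
      rho2 <- ((b[1] + b[3]) / 2 - (gx1[i] + gx2[i]) / 2)^2 +
        ((b[2] + b[4]) / 2 - (gy1[i] + gy2[i]) / 2)^2
      c2 <- (max(b[3], gx2[i]) - min(b[1], gx1[i]))^2 +
        (max(b[4], gy2[i]) - min(b[2], gy1[i]))^2 + 1e-9
      v <- 4 / pi^2 * (atan((gx2[i] - gx1[i]) / (gy2[i] - gy1[i])) -
                         atan((b[3] - b[1]) / (b[4] - b[2])))^2
      alpha <- v / (1 - iouv + v + 1e-9)
      1 - iouv + rho2 / c2 + alpha * v
    }, numeric(1))
    expect_equal(lv, direct, tolerance = 1e-8)
    # undetached composite over the same primitive set (atan, div, pmin/pmax)
    mk <- function() {
      l <- op_col(p, 1L); t <- op_col(p, 2L); r <- op_col(p, 3L); b <- op_col(p, 4L)
      iw <- op_clamp_min(op_sub(op_pmin2(r, tn_leaf(gx2)), op_pmax2(l, tn_leaf(gx1))), 0)
      ih <- op_clamp_min(op_sub(op_pmin2(b, tn_leaf(gy2)), op_pmax2(t, tn_leaf(gy1))), 0)
      inter <- op_mul(iw, ih)
      area <- op_mul(op_sub(r, l), op_sub(b, t))
      un <- op_scalar_add(op_sub(op_add(area, tn_leaf((gx2 - gx1) * (gy2 - gy1))), inter), 1e-9)
      iouv <- op_div(inter, un)
      vv <- op_square(op_sub(tn_leaf(atan((gx2 - gx1) / (gy2 - gy1))),
                             op_atan(op_div(op_sub(r, l), op_sub(b, t)))))
      op_dot_const(op_add(op_scalar_add(op_scalar_mul(iouv, -1), 1), vv), c(1, 1))
    }
    expect_lt(fd_check(mk, p, list(p), h = 1e-6), 1e-4)
  })
})

test_that("composite layer gradients (wtconv, SE, attention) are exact", {
  set.seed(13)
  tn_param <- giwtnet:::tn_param
  with(as.list(asNamespace("giwtnet")), {
    ly <- with_seed(3, nn_wtconv(wtconv_config(4, 5, 2)))
    ps <- collect_params(ly)
    xx <- tn_param(array(rnorm(7 * 9 * 2 * 4), c(7, 9, 2, 4)))  # odd sizes hit pad/crop
    lv <- c(list(xx), unname(ps))
    expect_lt(fd_check(function() op_sum(op_square(ly$forward(xx))), xx, lv), 1e-5)
    expect_lt(fd_check(function() op_sum(op_square(ly$forward(xx))), ps$lvl2_w, lv), 1e-5)
    se <- with_seed(4, nn_se(se_config(4, 2)))
    pse <- collect_params(se)
    ls <- c(list(xx), unname(pse))
    expect_lt(fd_check(function() op_sum(op_square(se$forward(xx))), pse$w1, ls), 1e-4)
    at <- with_seed(5, nn_attention(8, 2))
    pat <- collect_params(at)
    xa <- tn_param(array(rnorm(4 * 4 * 2 * 8) * 0.5, c(4, 4, 2, 8)))
    la <- c(list(xa), unname(pat))
    expect_lt(fd_check(function() op_sum(op_square(at$forward(xa, train = TRUE))), xa, la), 1e-2)
    expect_lt(fd_check(function() op_sum(op_square(at$forward(xa, train = TRUE))),
                       pat[["qkv.w"]], la), 1e-2)
  })
})
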