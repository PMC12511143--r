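# Orthonormal Haar analysis/synthesis and the WTConv operator.

test_that("haar_dwt2 matches the hand-evaluated separable filter bank", {
  # 2x2 input ((a,b),(c,d)) with a=1, b=2, c=3, d=4
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  b <- haar_dwt2(m)
  expect_equal(as.numeric(b$LL), (1 + 2 + 3 + 4) / 2)
  expect_equal(as.numeric(b$LH), (1 - 2 + 3 - 4) / 2)
  expect_equal(as.numeric(b$HL), (1 + 2 - 3 - 4) / 2)
  expect_equal(as.numeric(b$HH), (1 - 2 - 3 + 4) / 2)
  # constant map: LL = 2v, high bands vanish
  cb <- haar_dwt2(matrix(3.5, 6, 6))
  expect_equal(max(abs(cb$LL - 7)), 0)
  expect_equal(max(abs(cb$LH)), 0)
  expect_equal(max(abs(cb$HL)), 0)
  expect_equal(max(abs(cb$HH)), 0)
  # and its inverse: LL = 2v, zeros -> constant v
  rec <- haar_idwt2(cb)
  expect_equal(max(abs(rec - 3.5)), 0)
})

test_that("dwt agrees with a literal 2x2-block reference on random input", {
  set.seed(21)
  x <- array(runif(8 * 10 * 2 * 3, -1, 1), c(8, 10, 2, 3))
  b <- haar_dwt2(x)
  r <- ref_haar_dwt(x)
  for (nm in c("LL", "LH", "HL", "HH")) expect_lt(max(abs(b[[nm]] - r[[nm]])), 1e-12)
  expect_lt(max(abs(haar_idwt2(b) - ref_haar_idwt(r))), 1e-12)
})

test_that("perfect reconstruction and energy conservation hold, odd sizes included", {
  set.seed(22)
  for (i in 1:20) {
    d <- c(sample(3:17, 2), sample(1:2, 1), sample(1:3, 1))
    x <- array(runif(prod(d), -1, 1), d)
    b <- haar_dwt2(x)
    expect_lt(max(abs(haar_idwt2(b) - x)), 1e-6)
    if (all(d[1:2] %% 2 == 0)) {  # orthonormality only without padding
      e <- sum(b$LL^2) + sum(b$LH^2) + sum(b$HL^2) + sum(b$HH^2)
      expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
    }
  }
})

test_that("haar ops reject invalid inputs", {
  expect_error(haar_dwt2(array(1, c(0, 4, 1, 1))), "empty|non-positive")
  expect_error(haar_idwt2(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2),
                          matrix(1, 3, 3)), "identical shapes")
})

test_that("wtconv identity-kernel cascade doubles the input and zero kernels annihilate it", {
  cfg <- wtconv_config(4, 5, 1)
  ly <- giwtnet:::with_seed(1, giwtnet:::nn_wtconv(cfg))
  ly$params$base_w$v[] <- 0; ly$params$base_w$v[3, 3, ] <- 1
  ly$params$lvl1_w$v[] <- 0; ly$params$lvl1_w$v[3, 3, ] <- 1
  set.seed(5)
  x <- array(runif(8 * 8 * 2 * 4, -1, 1), c(8, 8, 2, 4))
  expect_lt(max(abs(wtconv(x, cfg, params = ly) - 2 * x)), 1e-5)
  ly$params$base_w$v[] <- 0; ly$params$lvl1_w$v[] <- 0
  expect_equal(max(abs(wtconv(x, cfg, params = ly))), 0)
})

test_that("wtconv forward matches the literal loop reference", {
  set.seed(6)
  for (L in 1:2) {
    cfg <- wtconv_config(4, 5, L)
    ly <- giwtnet:::with_seed(L, giwtnet:::nn_wtconv(cfg))
    x <- array(runif(8 * 8 * 2 * 4, -1, 1), c(8, 8, 2, 4))
    expect_lt(max(abs(wtconv(x, cfg, params = ly) - ref_wtconv(x, ly))), 1e-5)
  }
  # shape contract at L = 2
  cfg <- wtconv_config(3, 3, 2)
  x <- array(rnorm(12 * 12 * 1 * 3), c(12, 12, 1, 3))
  expect_identical(dim(wtconv(x, cfg)), dim(x))
  expect_error(wtconv(array(0, c(4, 4, 1, 2)), wtconv_config(4)), "channels")
})

test_that("parameter count is exact and grows linearly while the receptive field doubles", {
  expect_identical(wtconv_param_count(wtconv_config(32, 5, 1)), 4160L)
  expect_identical(wtconv_param_count(wtconv_config(1, 1, 1)), 10L)
  # enumeration oracle: count parameters of the constructed module
  for (k in c(3, 5)) for (L in 1:3) {
    cfg <- wtconv_config(8, k, L)
    ly <- giwtnet:::with_seed(0, giwtnet:::nn_wtconv(cfg))
    expect_identical(giwtnet::param_count(ly), wtconv_param_count(cfg))
  }
  counts <- vapply(1:4, function(L) wtconv_param_count(wtconv_config(16, 5, L)), integer(1))
  expect_true(all(diff(counts) == 4 * 16 * 25 + 4 * 16))
  rf <- vapply(1:4, function(L) wtconv_receptive_field(wtconv_config(16, 5, L)), integer(1))
  expect_equal(rf, c(9L, 17L, 33L, 65L))
  expect_identical(wtconv_receptive_field(wtconv_config(16, 5, 1), num_levels = 0), 5L)
})

test_that("receptive field matches a perturbation trace through the cascade", {
  # flip one input pixel and measure the span of changed outputs.  The
  # formula 2^L*(k-1)+1 counts the dilated-convolution equivalent span; the
  # block wavelet transform can extend it by up to one 2^L alignment block.
  for (L in 1:3) {
    cfg <- wtconv_config(1, 5, L)
    ly <- giwtnet:::with_seed(2, giwtnet:::nn_wtconv(cfg))
    n <- 128L
    x0 <- array(0, c(n, n, 1, 1))
    x1 <- x0; x1[n / 2, n / 2, 1, 1] <- 1
    dy <- abs(wtconv(x1, cfg, params = ly) - wtconv(x0, cfg, params = ly))
    rows <- which(apply(dy[, , 1, 1], 1, max) > 1e-12)
    span <- diff(range(rows)) + 1L
    rf <- wtconv_receptive_field(cfg)
    expect_gte(span, rf - 2^L + 1)
    expect_lte(span, rf + 2^L - 1)
    # and the span roughly doubles per added level (exponential growth)
    if (L > 1) expect_gt(span, wtconv_receptive_field(cfg, num_levels = L - 1))
  }
})
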