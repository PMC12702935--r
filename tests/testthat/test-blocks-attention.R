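test_that("adaptive ECA kernel size matches hand-evaluated cases", {
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(2), 1L)    # |1/2 + 1/2| = 1
  expect_identical(eca_kernel_size(1024), 5L) # floor(5.5) = 5, odd
  expect_identical(eca_kernel_size(8), 3L)    # floor(2) = 2, even -> 3
  expect_error(eca_kernel_size(0), "positive")
  expect_error(eca_kernel_size(-4), "positive")
})

test_that("ECA kernel size is odd and non-decreasing over channels 1..4096", {
  ks <- vapply(1:4096, eca_kernel_size, integer(1))
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(ks >= 1L))
  expect_true(all(diff(ks) >= 0L))
  # the k = 5 plateau covers the canonical channel counts
  expect_true(all(ks[c(256L, 512L, 768L, 1024L)] == 5L))
})

test_that("global average pooling reduces planes to their means", {
  expect_equal(global_avg_pool(array(3.5, c(4, 4, 2, 1))),
               matrix(3.5, 2, 1))
  expect_equal(global_avg_pool(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(2.5, 1, 1))
  expect_equal(global_avg_pool(array(0, c(5, 3, 4, 2))), matrix(0, 4, 2))
})

test_that("ECA with zero conv weights halves the input", {
  set.seed(1)
  blk <- nn_eca(8)
  blk$params$w$value[] <- 0
  x <- rand_map(5, 6, 8, 2)
  expect_equal(eca_forward(blk, x), 0.5 * x, tolerance = 1e-12)
})

test_that("ECA preserves shape and produces gates in (0,1)", {
  set.seed(2)
  for (C in c(3L, 17L, 64L)) {
    blk <- nn_eca(C)
    x <- rand_map(4, 7, C, 2)
    y <- eca_forward(blk, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
    w <- blk$channel_weights(x)
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("ECA matches the explicit dot-product oracle", {
  set.seed(3)
  for (rep in 1:5) {
    C <- sample(c(8L, 31L, 64L), 1L)
    blk <- nn_eca(C)
    x <- rand_map(sample(3:9, 1), sample(3:9, 1), C, sample(1:2, 1))
    expect_equal(eca_forward(blk, x), naive_eca(blk, x), tolerance = 1e-10)
  }
})

test_that("identical channels get identical interior ECA weights", {
  set.seed(4)
  C <- 32L
  blk <- nn_eca(C)
  plane <- matrix(rnorm(36), 6, 6)
  x <- array(rep(plane, C), c(6, 6, C, 1))
  w <- blk$channel_weights(x)
  pad <- (blk$k - 1L) %/% 2L
  interior <- w[(1L + pad):(C - pad), 1]
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("CBAM channel attention obeys its closed forms", {
  set.seed(5)
  blk <- nn_cbam(8, reduction = 4)
  x <- rand_map(6, 6, 8, 2)
  # zero MLP -> sigmoid(0 + 0) = 0.5 everywhere
  for (nm in c("W1", "b1", "W2", "b2")) blk$params[[nm]]$value[] <- 0
  expect_equal(cbam_channel_attention(blk, x), matrix(0.5, 8, 2))
  # 1-channel identity MLP on a constant plane c gives sigmoid(2c)
  one <- nn_cbam(1L, reduction = 1)
  one$params$W1$value[] <- 1; one$params$b1$value[] <- 0
  one$params$W2$value[] <- 1; one$params$b2$value[] <- 0
  cc <- 0.3
  expect_equal(as.numeric(cbam_channel_attention(one, array(cc, c(4, 4, 1, 1)))),
               plogis(2 * cc), tolerance = 1e-12)
})

test_that("CBAM channel attention matches the loop oracle and stays in (0,1)", {
  set.seed(6)
  blk <- nn_cbam(16, reduction = 4)
  x <- rand_map(5, 7, 16, 2)
  mc <- cbam_channel_attention(blk, x)
  expect_equal(mc, naive_cbam_channel(blk, x), tolerance = 1e-10)
  expect_true(all(mc > 0 & mc < 1))
})

test_that("CBAM spatial attention: zero conv gives 0.5, dims preserved, constant interior", {
  set.seed(7)
  blk <- nn_cbam(4)
  conv <- blk$children$conv_spatial
  x <- rand_map(9, 9, 4, 1)
  saved_w <- conv$params$w$value
  conv$params$w$value[] <- 0
  conv$params$b$value[] <- 0
  expect_equal(cbam_spatial_attention(blk, x), array(0.5, c(9, 9, 1, 1)))
  conv$params$w$value <- saved_w
  ms <- cbam_spatial_attention(blk, x)
  expect_identical(dim(ms), c(9L, 9L, 1L, 1L))
  expect_true(all(ms > 0 & ms < 1))
  # spatially constant input: interior of the 7x7 "same" conv is constant
  xc <- array(rep(0.7, 9 * 9 * 4), c(9, 9, 4, 1))
  msc <- cbam_spatial_attention(blk, xc)
  expect_lt(diff(range(msc[4:6, 4:6, 1, 1])), 1e-12)
})

test_that("CBAM forward composes channel-then-spatial gating", {
  set.seed(8)
  blk <- nn_cbam(12, reduction = 4)
  x <- rand_map(6, 8, 12, 2)
  y <- cbam_forward(blk, x)
  expect_identical(dim(y), dim(x))
  # equals the explicit two-step composition via the public attention ops
  mc <- cbam_channel_attention(blk, x)
  xp <- x
  for (n in 1:2) for (c in 1:12) xp[, , c, n] <- x[, , c, n] * mc[c, n]
  ms <- cbam_spatial_attention(blk, xp)
  ref <- xp
  for (c in 1:12) ref[, , c, ] <- xp[, , c, ] * ms[, , 1, ]
  expect_equal(y, ref, tolerance = 1e-12)
  # and matches the independent loop oracle
  expect_equal(y, naive_cbam(blk, x), tolerance = 1e-10)
})

test_that("zero-initialised CBAM scales the input by 0.25", {
  set.seed(9)
  blk <- nn_cbam(6, reduction = 2)
  set_params_zero(blk)
  x <- rand_map(5, 5, 6, 1)
  expect_equal(cbam_forward(blk, x), 0.25 * x, tolerance = 1e-12)
})

test_that("near-saturated CBAM gates approach the identity", {
  set.seed(10)
  blk <- nn_cbam(4, reduction = 2)
  set_params_zero(blk)
  blk$params$b2$value[] <- 50               # channel gate -> 1
  blk$children$conv_spatial$params$b$value[] <- 50  # spatial gate -> 1
  x <- rand_map(5, 5, 4, 1)
  expect_equal(cbam_forward(blk, x), x, tolerance = 1e-9)
})

test_that("spatial-first CBAM order is available and differs", {
  set.seed(11)
  blk_cf <- nn_cbam(8, reduction = 2, order = "channel_first")
  set.seed(11)
  blk_sf <- nn_cbam(8, reduction = 2, order = "spatial_first")
  x <- rand_map(6, 6, 8, 1)
  expect_false(isTRUE(all.equal(cbam_forward(blk_cf, x),
                                cbam_forward(blk_sf, x))))
})

test_that("the SE drop-in gate scales channels within (0,1)", {
  set.seed(12)
  blk <- nn_se(8, reduction = 2)
  x <- rand_map(5, 5, 8, 2)
  y <- block_forward(blk, x)
  expect_identical(dim(y), dim(x))
  # zero MLP: every gate is exactly 0.5
  set_params_zero(blk)
  expect_equal(block_forward(blk, x), 0.5 * x, tolerance = 1e-12)
  expect_identical(count_parameters(nn_se(16, 4)),
                   as.numeric(16 * 4 + 4 + 4 * 16 + 16))
})
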