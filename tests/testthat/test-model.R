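# Small presets for fast structural tests: 32x32 input, width 0.125.
tiny_cfg <- function(...) {
  model_config(num_classes = 4, input_size = 32, width = 0.125, ...)
}

test_that("configuration validation names the offending field", {
  expect_error(model_config(num_classes = 1), "num_classes")
  expect_error(model_config(num_classes = 4, input_size = 100), "patch_size|input_size")
  expect_error(model_config(num_classes = 4, patch_size = 8), "patch_size")
  expect_error(model_config(num_classes = 4,
                            decoder_channels = c(64, 32)), "decoder_channels")
})

test_that("hybrid encoder yields the contracted token counts and skip shapes", {
  m <- build_model(tiny_cfg(), seed = 1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  enc <- hybrid_encode(m, x)
  expect_identical(dim(enc$tokens), c(4L, m$cfg$dim, 2L))  # (32/16)^2 tokens
  # skips at 1/8, 1/4, 1/2 resolution (decoder order)
  expect_identical(dim(enc$skips[[1]])[1:2], c(4L, 4L))
  expect_identical(dim(enc$skips[[2]])[1:2], c(8L, 8L))
  expect_identical(dim(enc$skips[[3]])[1:2], c(16L, 16L))
  m64 <- build_model(model_config(num_classes = 4, input_size = 64,
                                  width = 0.125), seed = 1)
  enc64 <- hybrid_encode(m64, array(0, c(64, 64, 3, 1)))
  expect_identical(dim(enc64$tokens)[1], 16L)
  expect_error(hybrid_encode(m, array(0, c(64, 64, 3, 1))), "input_size")
})

test_that("bottleneck reshapes tokens and only adds CBAM-ASPP parameters", {
  m_off <- build_model(tiny_cfg(use_cbam_aspp = FALSE), seed = 1)
  tok <- array(rnorm(4 * m_off$cfg$dim * 1), c(4, m_off$cfg$dim, 1))
  bot <- model_bottleneck(m_off, tok)
  expect_identical(dim(bot), c(2L, 2L, m_off$cfg$dim, 1L))
  expect_equal(as.vector(bot), as.vector(tok))  # identity reshape
  expect_error(model_bottleneck(m_off, array(0, c(3, 8, 1))),
               "perfect square")
  m_on <- build_model(tiny_cfg(use_cbam_aspp = TRUE), seed = 1)
  diff <- count_parameters(m_on) - count_parameters(m_off)
  expect_identical(diff, count_parameters(m_on$net$children$cbam_aspp))
})

test_that("decoder returns full resolution and the head gives per-pixel softmax", {
  m <- build_model(tiny_cfg(), seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  lg <- model_forward(m, x)
  expect_identical(dim(lg), c(32L, 32L, 4L, 2L))
  expect_true(all(is.finite(lg)))
  pr <- model_prob(m, x)
  sums <- apply(pr, c(1, 2, 4), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-10)
  lab <- predict_labels(m, x)
  expect_true(all(lab >= 0 & lab < 4))
})

test_that("toggles order parameter counts as the ablation expects", {
  for (preset in c("paper-text", "wide")) {
    base <- count_parameters(build_model(tiny_cfg(
      preset = preset, use_eca = FALSE, use_cbam_aspp = FALSE,
      use_dsc = FALSE), seed = 1))
    eca <- count_parameters(build_model(tiny_cfg(
      preset = preset, use_eca = TRUE, use_cbam_aspp = FALSE,
      use_dsc = FALSE), seed = 1))
    cbam <- count_parameters(build_model(tiny_cfg(
      preset = preset, use_eca = FALSE, use_cbam_aspp = TRUE,
      use_dsc = FALSE), seed = 1))
    dsc <- count_parameters(build_model(tiny_cfg(
      preset = preset, use_eca = FALSE, use_cbam_aspp = FALSE,
      use_dsc = TRUE), seed = 1))
    expect_gt(eca, base)
    expect_gt(cbam, base)
    expect_lt(dsc, base)
  }
})

test_that("toggling separable decoding changes only decoder convolutions", {
  m_std <- build_model(tiny_cfg(use_dsc = FALSE), seed = 1)
  m_dsc <- build_model(tiny_cfg(use_dsc = TRUE), seed = 1)
  t_std <- layer_table(m_std)
  t_dsc <- layer_table(m_dsc)
  merged <- merge(t_std, t_dsc, by = "name", suffixes = c(".std", ".dsc"))
  changed <- merged$name[merged$params.std != merged$params.dsc]
  expect_true(all(grepl("^dec", changed)))
  only_std <- setdiff(t_std$name, t_dsc$name)
  only_dsc <- setdiff(t_dsc$name, t_std$name)
  expect_true(all(grepl("^dec", c(only_std, only_dsc))))
})

test_that("forward is deterministic and the checkpoint round-trips bit-exactly", {
  m1 <- build_model(tiny_cfg(), seed = 7)
  m2 <- build_model(tiny_cfg(), seed = 7)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(model_forward(m1, x), model_forward(m2, x))
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m1, ck)
  m3 <- load_checkpoint(ck)
  expect_identical(model_forward(m1, x), model_forward(m3, x))
})

test_that("gradient reaches every learnable array in the full model", {
  m <- build_model(tiny_cfg(), seed = 3)
  params <- module_params(m)
  set.seed(3)
  x <- hybridseg:::tensor_const(array(runif(32 * 32 * 3 * 2),
                                      c(32, 32, 3, 2)))
  y <- array(sample(0:3, 32 * 32 * 2, TRUE), c(32, 32, 2))
  loss <- hybridseg:::op_seg_loss(hybridseg:::graph_forward(m, x, TRUE), y)
  hybridseg:::backward(loss)
  dead <- names(params)[vapply(params, function(p) {
    is.null(p$grad) || all(p$grad == 0)
  }, logical(1))]
  expect_identical(dead, character(0))
})

test_that("stage-level ECA placement builds and differs from block placement", {
  m_blk <- build_model(tiny_cfg(eca_placement = "block"), seed = 4)
  m_stg <- build_model(tiny_cfg(eca_placement = "stage"), seed = 4)
  ps <- names(module_params(m_stg))
  expect_true(any(grepl("^eca_enc", ps)))
  expect_false(any(grepl("^eca_enc", names(module_params(m_blk)))))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(dim(model_forward(m_stg, x)), c(32L, 32L, 4L, 1L))
})

test_that("all eight toggle variants build and produce full-resolution logits", {
  grid <- expand.grid(eca = c(FALSE, TRUE), cbam = c(FALSE, TRUE),
                      dsc = c(FALSE, TRUE))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  for (i in seq_len(nrow(grid))) {
    m <- build_model(tiny_cfg(use_eca = grid$eca[i],
                              use_cbam_aspp = grid$cbam[i],
                              use_dsc = grid$dsc[i]), seed = 1)
    lg <- model_forward(m, x)
    expect_identical(dim(lg), c(32L, 32L, 4L, 1L))
    expect_true(all(is.finite(lg)))
  }
})
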