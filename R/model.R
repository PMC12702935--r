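# ---------------------------------------------------------------------------
# Full network assembly: CNN(+ECA) hybrid encoder, transformer stack,
# optional CBAM-ASPP bottleneck, cascaded decoder with skip connections
# (standard or depthwise-separable convolutions, optional ECA), 3x3
# segmentation head.  The three toggles reproduce the eight ablation
# variants between the plain baseline (all off) and the full model (all on).
# ---------------------------------------------------------------------------

scale_ch <- function(c0, width) max(1L, as.integer(round(c0 * width)))

#' Architecture configuration
#'
#' @param num_classes number of segmentation classes including background
#' @param in_channels image channels (default 3)
#' @param input_size square input side, divisible by `patch_size`
#' @param patch_size tokenisation patch size; the hybrid encoder realises a
#'   fixed 1/16 tokenisation, so this must be 16
#' @param preset transformer preset: `"paper-text"` (dim 512, MLP 2048,
#'   8 heads) or `"wide"` (dim 768, MLP 3072, 12 heads)
#' @param n_layers transformer depth
#' @param n_heads attention heads; default from the preset.  The embedding
#'   dimension must be divisible by the head count, which is why the
#'   512-dim preset carries 8 heads rather than 12
#' @param decoder_channels output widths of the four decoder stages
#' @param use_eca,use_cbam_aspp,use_dsc the three architecture toggles; all
#'   off is the plain baseline, all on the full model
#' @param width width multiplier applied to every channel count (and to the
#'   transformer dims, rounded to a multiple of the head count) for
#'   desk-scale runs.  Decoder stage widths are floored at 16 channels (the
#'   ladder's own final width): the multiplier targets the heavy encoder,
#'   and thinning the per-pixel classifier below that degrades class
#'   separation out of proportion to its cost
#' @param aspp_rates dilation rates of the bottleneck pyramid
#' @param cbam_reduction,cbam_order CBAM hyperparameters
#' @param eca_gamma,eca_b ECA kernel-size adaptation parameters
#' @param dec1_depth_groups groups of the first decoder convolution's
#'   spatial stage when `use_dsc` (default: full depthwise)
#' @param eca_placement where encoder ECA gates sit: `"block"` (default)
#'   gates each bottleneck's residual branch before the identity addition,
#'   as in the reference ECA design; `"stage"` gates whole stage outputs
#' @param pos_encoding `"sinusoidal"` (fixed, default) or `"learned"`
#' @param dropout transformer dropout rate (0 keeps runs deterministic)
#' @param prenorm pre-norm (default) vs post-norm encoder layers
#' @return an object of class `model_config`
#' @export
model_config <- function(num_classes,
                         in_channels = 3L,
                         input_size = 256L,
                         patch_size = 16L,
                         preset = c("paper-text", "wide"),
                         n_layers = 12L,
                         n_heads = NULL,
                         decoder_channels = c(256L, 128L, 64L, 16L),
                         use_eca = TRUE,
                         use_cbam_aspp = TRUE,
                         use_dsc = TRUE,
                         width = 1,
                         aspp_rates = c(1L, 2L, 4L, 8L),
                         cbam_reduction = 16,
                         cbam_order = "channel_first",
                         eca_gamma = 2,
                         eca_b = 1,
                         dec1_depth_groups = NULL,
                         eca_placement = c("block", "stage"),
                         pos_encoding = c("sinusoidal", "learned"),
                         dropout = 0,
                         prenorm = TRUE) {
  preset <- match.arg(preset)
  eca_placement <- match.arg(eca_placement)
  pos_encoding <- match.arg(pos_encoding)
  if (num_classes < 2) stop("num_classes must be at least 2")
  if (patch_size != 16L) {
    stop("patch_size must be 16: the hybrid encoder tokenises at 1/16")
  }
  if (input_size %% patch_size != 0) {
    stop("input_size must be divisible by patch_size")
  }
  if (length(decoder_channels) != 4L) {
    stop("decoder_channels must list the four stage widths")
  }
  dims <- switch(preset,
    "paper-text" = list(dim = 512L, mlp = 2048L, heads = 8L),
    "wide" = list(dim = 768L, mlp = 3072L, heads = 12L))
  n_heads <- as.integer(n_heads %||% dims$heads)
  dim_e <- max(n_heads, as.integer(round(dims$dim * width / n_heads)) * n_heads)
  mlp_e <- max(n_heads, scale_ch(dims$mlp, width))
  if (dim_e %% n_heads != 0) stop("embedding dim not divisible by n_heads")
  cfg <- list(num_classes = as.integer(num_classes),
              in_channels = as.integer(in_channels),
              input_size = as.integer(input_size),
              patch_size = as.integer(patch_size),
              preset = preset, n_layers = as.integer(n_layers),
              n_heads = n_heads, dim = dim_e, mlp_dim = mlp_e,
              decoder_channels = vapply(decoder_channels, function(c0) {
                max(min(as.integer(c0), 16L), scale_ch(c0, width))
              }, integer(1)),
              use_eca = isTRUE(use_eca),
              use_cbam_aspp = isTRUE(use_cbam_aspp),
              use_dsc = isTRUE(use_dsc),
              width = width, aspp_rates = as.integer(aspp_rates),
              cbam_reduction = cbam_reduction, cbam_order = cbam_order,
              eca_gamma = eca_gamma, eca_b = eca_b,
              dec1_depth_groups = dec1_depth_groups,
              eca_placement = eca_placement,
              pos_encoding = pos_encoding, dropout = dropout,
              prenorm = prenorm)
  structure(cfg, class = "model_config")
}

# One ResNet bottleneck residual block (1x1 -> 3x3 -> 1x1 + projection).
# With `eca`, the channel gate is applied to the residual branch before the
# identity addition -- the reference ECA placement, which leaves the
# identity path ungated.
nn_res_block <- function(in_ch, mid, out_ch, stride = 1L, eca = FALSE,
                         eca_gamma = 2, eca_b = 1) {
  ch <- list(
    conv1 = nn_conv2d(in_ch, mid, 1L, bias = FALSE),
    bn1 = nn_batchnorm2d(mid),
    conv2 = nn_conv2d(mid, mid, 3L, stride = stride, bias = FALSE),
    bn2 = nn_batchnorm2d(mid),
    conv3 = nn_conv2d(mid, out_ch, 1L, bias = FALSE),
    bn3 = nn_batchnorm2d(out_ch)
  )
  if (eca) ch$eca <- nn_eca(out_ch, eca_gamma, eca_b)
  project <- (in_ch != out_ch) || stride != 1L
  if (project) {
    ch$proj <- nn_conv2d(in_ch, out_ch, 1L, stride = stride, bias = FALSE)
    ch$bn_proj <- nn_batchnorm2d(out_ch)
  }
  m <- new_module("res_block", children = ch,
                  meta = list(type = "res_block", out_ch = out_ch))
  m$fwd <- function(x, training = FALSE) {
    y <- op_relu(ch$bn1$fwd(ch$conv1$fwd(x, training), training))
    y <- op_relu(ch$bn2$fwd(ch$conv2$fwd(y, training), training))
    y <- ch$bn3$fwd(ch$conv3$fwd(y, training), training)
    if (eca) y <- ch$eca$fwd(y, training)
    s <- if (project) ch$bn_proj$fwd(ch$proj$fwd(x, training), training) else x
    op_relu(op_add(y, s))
  }
  m
}

nn_res_stage <- function(in_ch, mid, out_ch, n_blocks, stride,
                         eca = FALSE, eca_gamma = 2, eca_b = 1) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- nn_res_block(in_ch, mid, out_ch, stride, eca,
                              eca_gamma, eca_b)
  for (i in seq_len(n_blocks - 1L) + 1L) {
    blocks[[i]] <- nn_res_block(out_ch, mid, out_ch, 1L, eca,
                                eca_gamma, eca_b)
  }
  nn_seq(blocks)
}

# Decoder conv unit.  Standard: 3x3 conv + BN + ReLU.  Separable: the
# depthwise and pointwise stages each carry BN + ReLU (the usual separable
# conv arrangement, which trains markedly better than the bare pair).
nn_dec_conv <- function(in_ch, out_ch, use_dsc, depth_groups = NULL) {
  if (use_dsc) {
    dw <- nn_conv2d(in_ch, in_ch, 3L, groups = depth_groups %||% in_ch,
                    bias = FALSE)
    m <- new_module("dec_conv",
                    children = list(conv_dw = dw,
                                    bn_mid = nn_batchnorm2d(in_ch),
                                    conv_pw = nn_conv2d(in_ch, out_ch, 1L,
                                                        bias = FALSE),
                                    bn = nn_batchnorm2d(out_ch)),
                    meta = list(type = "dec_conv", out_ch = out_ch))
    m$fwd <- function(x, training = FALSE) {
      ch <- m$children
      y <- op_relu(ch$bn_mid$fwd(ch$conv_dw$fwd(x, training), training))
      op_relu(ch$bn$fwd(ch$conv_pw$fwd(y, training), training))
    }
  } else {
    conv <- nn_conv2d(in_ch, out_ch, 3L, bias = FALSE)
    bn <- nn_batchnorm2d(out_ch)
    m <- new_module("dec_conv", children = list(conv = conv, bn = bn),
                    meta = list(type = "dec_conv", out_ch = out_ch))
    m$fwd <- function(x, training = FALSE) {
      op_relu(bn$fwd(conv$fwd(x, training), training))
    }
  }
  m
}

#' Build the segmentation model
#'
#' Assembles the hybrid encoder (stem + four residual stages with optional
#' per-stage ECA, deepest map tokenised and run through the transformer
#' stack), the optional CBAM-ASPP bottleneck, the cascaded decoder and the
#' 3x3 segmentation head, per the configuration's toggles.
#'
#' @param cfg a [model_config()]
#' @param seed integer controlling all weight initialisation
#' @return an object of class `hs_model`
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  w <- cfg$width
  c0 <- scale_ch(64L, w)
  mids <- vapply(c(64L, 128L, 256L, 512L), scale_ch, integer(1), width = w)
  outs <- 4L * mids
  dec <- cfg$decoder_channels

  block_eca <- cfg$use_eca && cfg$eca_placement == "block"
  ch <- list(
    stem_conv = nn_conv2d(cfg$in_channels, c0, 7L, stride = 2L, bias = FALSE),
    stem_bn = nn_batchnorm2d(c0),
    stage1 = nn_res_stage(c0, mids[1], outs[1], 3L, 2L, block_eca,
                          cfg$eca_gamma, cfg$eca_b),
    stage2 = nn_res_stage(outs[1], mids[2], outs[2], 4L, 2L, block_eca,
                          cfg$eca_gamma, cfg$eca_b),
    stage3 = nn_res_stage(outs[2], mids[3], outs[3], 6L, 2L, block_eca,
                          cfg$eca_gamma, cfg$eca_b),
    stage4 = nn_res_stage(outs[3], mids[4], outs[4], 3L, 1L, block_eca,
                          cfg$eca_gamma, cfg$eca_b),
    patch_embed = nn_conv2d(outs[4], cfg$dim, 1L, bias = TRUE)
  )
  if (cfg$use_eca && cfg$eca_placement == "stage") {
    enc_ch <- c(c0, outs)
    for (i in seq_along(enc_ch)) {
      ch[[sprintf("eca_enc%d", i - 1L)]] <-
        nn_eca(enc_ch[i], cfg$eca_gamma, cfg$eca_b)
    }
  }
  ch$encoder <- nn_encoder_stack(cfg$dim, cfg$n_heads, cfg$mlp_dim,
                                 cfg$n_layers, cfg$dropout, cfg$prenorm)
  n_tokens <- (cfg$input_size %/% 16L)^2
  if (cfg$pos_encoding == "learned") {
    ch$pe <- new_module("pos_embed",
                        params = list(pe = tensor_param(
                          array(stats::rnorm(n_tokens * cfg$dim, 0, 0.02),
                                c(n_tokens, cfg$dim)))),
                        meta = list(type = "pos_embed"))
    ch$pe$fwd <- function(x, training = FALSE) op_add_pe(x, ch$pe$params$pe)
  }
  if (cfg$use_cbam_aspp) {
    ch$cbam_aspp <- nn_cbam_aspp(cfg$dim, out_ch = cfg$dim,
                                 rates = cfg$aspp_rates,
                                 reduction = cfg$cbam_reduction,
                                 order = cfg$cbam_order)
  }
  skips_ch <- c(outs[2], outs[1], c0)  # at 1/8, 1/4, 1/2
  ch$dec_in <- nn_dec_conv(cfg$dim, dec[1], cfg$use_dsc,
                           cfg$dec1_depth_groups)
  dec_in_ch <- c(dec[1] + skips_ch[1], dec[1] + skips_ch[2],
                 dec[2] + skips_ch[3], dec[3])
  dec_out_ch <- c(dec[1], dec[2], dec[3], dec[4])
  for (i in 1:4) {
    ch[[sprintf("dec%d", i)]] <- nn_dec_conv(dec_in_ch[i], dec_out_ch[i],
                                             cfg$use_dsc)
  }
  if (cfg$use_eca) {
    dec_eca_ch <- c(dec[1], dec_out_ch)
    for (i in seq_along(dec_eca_ch)) {
      ch[[sprintf("eca_dec%d", i - 1L)]] <-
        nn_eca(dec_eca_ch[i], cfg$eca_gamma, cfg$eca_b)
    }
  }
  ch$head <- nn_conv2d(dec[4], cfg$num_classes, 3L, bias = TRUE)
  ch$head$params$b$value[] <- 0

  net <- new_module("net", children = ch)
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$net <- net
  model$pe_matrix <- sinusoidal_pe(n_tokens, cfg$dim)
  model$up_cache <- new.env(parent = emptyenv())
  class(model) <- "hs_model"
  model
}

up_mats <- function(model, H, W) {
  key <- sprintf("%dx%d", H, W)
  m <- model$up_cache[[key]]
  if (is.null(m)) {
    m <- list(ri = bilinear_idx(2L * H, H), ci = bilinear_idx(2L * W, W))
    model$up_cache[[key]] <- m
  }
  m
}

# --- graph builders (tensor in / tensor out) -------------------------------

graph_encode <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  ch <- model$net$children
  d <- dim(x$value)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop(sprintf("input_size mismatch: model expects %d, image is %dx%d",
                 cfg$input_size, d[1], d[2]))
  }
  eca <- function(i, t) {
    if (cfg$use_eca && cfg$eca_placement == "stage") {
      ch[[sprintf("eca_enc%d", i)]]$fwd(t, training)
    } else {
      t
    }
  }
  s1 <- eca(0L, op_relu(ch$stem_bn$fwd(ch$stem_conv$fwd(x, training),
                                       training)))
  s2 <- eca(1L, ch$stage1$fwd(s1, training))
  s3 <- eca(2L, ch$stage2$fwd(s2, training))
  deep <- eca(3L, ch$stage3$fwd(s3, training))
  deep <- eca(4L, ch$stage4$fwd(deep, training))
  emb <- ch$patch_embed$fwd(deep, training)
  de <- dim(emb$value)
  tokens <- op_reshape(emb, c(de[1] * de[2], de[3], de[4]))
  tokens <- if (cfg$pos_encoding == "learned") {
    ch$pe$fwd(tokens, training)
  } else {
    op_add_pe(tokens, model$pe_matrix)
  }
  tokens <- ch$encoder$fwd(tokens, training)
  list(tokens = tokens, skips = list(s3, s2, s1), grid = de[1:2])
}

graph_bottleneck <- function(model, tokens, training = FALSE) {
  cfg <- model$cfg
  d <- dim(tokens$value)
  side <- sqrt(d[1])
  if (side != floor(side)) stop("token count must be a perfect square")
  side <- as.integer(side)
  bottom <- op_reshape(tokens, c(side, side, d[2], d[3]))
  if (cfg$use_cbam_aspp) {
    bottom <- model$net$children$cbam_aspp$fwd(bottom, training)
  }
  bottom
}

graph_decode <- function(model, bottom, skips, training = FALSE) {
  cfg <- model$cfg
  ch <- model$net$children
  eca <- function(i, t) {
    if (cfg$use_eca) ch[[sprintf("eca_dec%d", i)]]$fwd(t, training) else t
  }
  y <- eca(0L, ch$dec_in$fwd(bottom, training))
  for (i in 1:4) {
    d <- dim(y$value)
    um <- up_mats(model, d[1], d[2])
    y <- op_upsample2x(y, um$ri, um$ci)
    if (i <= length(skips) && !is.null(skips[[i]])) {
      y <- op_concat_c(list(y, skips[[i]]))
    }
    y <- eca(i, ch[[sprintf("dec%d", i)]]$fwd(y, training))
  }
  ch$head$fwd(y, training)
}

graph_forward <- function(model, x, training = FALSE) {
  enc <- graph_encode(model, x, training)
  bottom <- graph_bottleneck(model, enc$tokens, training)
  graph_decode(model, bottom, enc$skips, training)
}

# --- public array API -------------------------------------------------------

#' Hybrid encoder: image to tokens plus skip features
#'
#' Runs the CNN backbone (with per-stage ECA when enabled), tokenises the
#' 1/16-resolution map, adds positional encoding and applies the
#' transformer stack.
#'
#' @param model an `hs_model`
#' @param image array `(H, W, C, N)` with `H = W = input_size`
#' @return list with `tokens` (`(n_tokens, dim, N)`) and `skips` (feature
#'   maps at 1/8, 1/4 and 1/2 resolution, in decoder order)
#' @export
hybrid_encode <- function(model, image) {
  enc <- graph_encode(model, tensor_const(as_featuremap(image)), FALSE)
  list(tokens = as_value(enc$tokens),
       skips = lapply(enc$skips, as_value))
}

#' Bottleneck: tokens back to a spatial map, optionally CBAM-ASPP refined
#'
#' @param model an `hs_model`
#' @param tokens array `(n_tokens, dim, N)`; the token count must be a
#'   perfect square
#' @return feature map `(side, side, dim, N)`
#' @export
model_bottleneck <- function(model, tokens) {
  as_value(graph_bottleneck(model, tensor_const(tokens), FALSE))
}

#' Decoder: cascaded upsampling with skip fusion and segmentation head
#'
#' @param model an `hs_model`
#' @param bottom bottleneck feature map `(side, side, dim, N)`
#' @param skips list of skip maps at 1/8, 1/4, 1/2 resolution (may contain
#'   `NULL` entries)
#' @return logits array `(input_size, input_size, num_classes, N)`
#' @export
model_decode <- function(model, bottom, skips) {
  as_value(graph_decode(model, tensor_const(bottom),
                        lapply(skips, function(s) {
                          if (is.null(s)) NULL else tensor_const(s)
                        }), FALSE))
}

#' Full forward pass to per-pixel class logits
#'
#' @param model an `hs_model`
#' @param image array `(H, W, C, N)`; lower-rank arrays are promoted
#' @return logits array `(H, W, num_classes, N)`
#' @export
model_forward <- function(model, image) {
  as_value(graph_forward(model, tensor_const(as_featuremap(image)), FALSE))
}

#' Per-pixel class probabilities
#' @param model an `hs_model`
#' @param image input array
#' @return array `(H, W, num_classes, N)` with per-pixel softmax over classes
#' @export
model_prob <- function(model, image) {
  lg <- model_forward(model, image)
  d <- dim(lg)
  p <- array(0, d)
  for (n in seq_len(d[4])) {
    p[, , , n] <- array(softmax_rows(matrix(array(lg[, , , n],
                                                  c(d[1] * d[2], d[3])),
                                            d[1] * d[2], d[3])),
                        c(d[1], d[2], d[3]))
  }
  p
}

#' Predicted label map
#' @param object an `hs_model`
#' @param image input array `(H, W, C, N)`
#' @param ... unused
#' @return integer array `(H, W, N)` of class labels in `[0, num_classes)`
#' @export
predict_labels <- function(object, image, ...) {
  lg <- model_forward(object, image)
  d <- dim(lg)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    m <- matrix(array(lg[, , , n], c(d[1] * d[2], d[3])), d[1] * d[2], d[3])
    out[, , n] <- array(max.col(m, ties.method = "first") - 1L, c(d[1], d[2]))
  }
  out
}

# --- checkpointing ---------------------------------------------------------

#' Save model parameters, buffers and configuration
#' @param model an `hs_model`
#' @param path file to write (RDS)
#' @export
save_checkpoint <- function(model, path) {
  ps <- module_params(model)
  bufs <- module_buffers(model)
  saveRDS(list(cfg = model$cfg,
               params = lapply(ps, function(p) p$value),
               buffers = lapply(bufs, function(b) list(mean = b$mean,
                                                       var = b$var))),
          path)
  invisible(path)
}

#' Restore a model from a checkpoint
#' @param path RDS file from [save_checkpoint()]
#' @return an `hs_model` with restored parameters and running statistics
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, seed = 0L)
  ps <- module_params(model)
  stopifnot(identical(names(ps), names(ck$params)))
  for (nm in names(ps)) ps[[nm]]$value <- ck$params[[nm]]
  bufs <- module_buffers(model)
  stopifnot(identical(names(bufs), names(ck$buffers)))
  for (nm in names(bufs)) {
    bufs[[nm]]$mean <- ck$buffers[[nm]]$mean
    bufs[[nm]]$var <- ck$buffers[[nm]]$var
  }
  model
}
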