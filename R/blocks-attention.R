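# ---------------------------------------------------------------------------
# Channel and spatial attention blocks: ECA and CBAM.
# ---------------------------------------------------------------------------

#' Adaptive kernel size for efficient channel attention
#'
#' ECA gates channels with a k-tap 1-D convolution over the global-average
#' pooled channel descriptor; the tap count adapts to the channel count as
#' `k = |log2(C)/gamma + b/gamma|_odd`.  The "nearest odd" operation is
#' ambiguous at half-integer ties, so the convention here (and the single
#' place ties are broken) is: take the floor, then add 1 if even.  This
#' yields k = 5 for C in {181..1448}, including the canonical C = 256.
#'
#' @param channels positive integer channel count
#' @param gamma,b slope and intercept of the adaptation rule (defaults 2, 1)
#' @return odd positive integer kernel size
#' @examples
#' eca_kernel_size(256)   # 5
#' eca_kernel_size(2)     # 1
#' eca_kernel_size(1024)  # 5
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  if (length(channels) != 1L || !is.finite(channels) || channels < 1) {
    stop("channels must be a positive integer")
  }
  if (gamma <= 0) stop("gamma must be positive")
  t <- abs(log2(channels) / gamma + b / gamma)
  k <- floor(t)
  if (k %% 2 == 0) k <- k + 1
  as.integer(max(1, k))
}

#' Global average pooling of a feature map
#'
#' Reduces each `H x W` channel plane to its mean, producing one descriptor
#' per channel and batch element.
#'
#' @param x feature map array `(H, W, C, N)` (lower-rank arrays are promoted)
#' @return matrix `(C, N)` of per-channel means
#' @export
global_avg_pool <- function(x) {
  x <- as_featuremap(x)
  d <- dim(x)
  array(colMeans(array(x, c(d[1] * d[2], d[3] * d[4]))), c(d[3], d[4]))
}

# 1-D convolution along the channel axis of a (C, N) descriptor, zero
# "same" padding, no bias: the ECA cross-channel interaction.
op_conv1d_channels <- function(x, w) {
  xv <- x$value; wv <- w$value
  C <- nrow(xv)
  k <- length(wv)
  pad <- (k - 1L) %/% 2L
  v <- array(0, dim(xv))
  for (j in seq_len(k)) {
    off <- j - 1L - pad
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    if (!any(ok)) next
    v[ok, ] <- v[ok, ] + wv[j] * xv[src[ok], , drop = FALSE]
  }
  new_tensor(v, list(x, w), function(g) {
    dx <- array(0, dim(xv))
    dw <- numeric(k)
    for (j in seq_len(k)) {
      off <- j - 1L - pad
      src <- seq_len(C) + off
      ok <- src >= 1L & src <= C
      if (!any(ok)) next
      dx[src[ok], ] <- dx[src[ok], , drop = FALSE] + wv[j] * g[ok, , drop = FALSE]
      dw[j] <- sum(g[ok, , drop = FALSE] * xv[src[ok], , drop = FALSE])
    }
    list(dx, array(dw, k))
  })
}

#' Efficient channel attention (ECA) block
#'
#' Gates each channel by `sigmoid(C1D_k(GAP(x)))` where the 1-D convolution
#' runs along the channel axis with an adaptively chosen kernel size and no
#' bias.
#'
#' @param channels input/output channel count
#' @param gamma,b kernel-size adaptation parameters; see [eca_kernel_size()]
#' @export
nn_eca <- function(channels, gamma = 2, b = 1) {
  k <- eca_kernel_size(channels, gamma, b)
  params <- list(w = tensor_param(array(stats::runif(k, -sqrt(6 / k),
                                                     sqrt(6 / k)), k)))
  m <- new_module("eca", params,
                  meta = list(type = "eca", out_ch = channels, k = k,
                              macs_per_px = 0))
  m$k <- k
  m$channel_weights <- function(x) {
    g <- tensor_const(global_avg_pool(as_featuremap(x)))
    as_value(op_sigmoid(op_conv1d_channels(g, m$params$w)))
  }
  m$fwd <- function(x, training = FALSE) {
    wch <- op_sigmoid(op_conv1d_channels(op_gap(x), m$params$w))
    op_scale_channels(x, wch)
  }
  m
}

#' Apply an ECA block to a feature map
#' @param block module from [nn_eca()]
#' @param x feature map array `(H, W, C, N)`
#' @return array of the same shape, scaled per channel
#' @export
eca_forward <- function(block, x) block_forward(block, x)

#' Convolutional block attention module (CBAM)
#'
#' Sequential channel and spatial gating.  The channel gate is
#' `sigmoid(MLP(avgpool) + MLP(maxpool))` with one shared two-layer
#' perceptron; the spatial gate concatenates channel-wise mean and max maps
#' and passes them through a single 7x7 convolution and sigmoid.  Channel
#' attention is applied first by default; `order = "spatial_first"` swaps
#' the two gates.
#'
#' @param channels input channel count
#' @param reduction hidden-layer reduction ratio of the shared MLP
#' @param spatial_kernel kernel size of the spatial-gate convolution
#' @param order `"channel_first"` (default) or `"spatial_first"`
#' @export
nn_cbam <- function(channels, reduction = 16, spatial_kernel = 7L,
                    order = c("channel_first", "spatial_first")) {
  order <- match.arg(order)
  hid <- max(1L, channels %/% reduction)
  params <- list(
    W1 = tensor_param(init_xavier(c(hid, channels), channels, hid)),
    b1 = tensor_param(array(0, hid)),
    W2 = tensor_param(init_xavier(c(channels, hid), hid, channels)),
    b2 = tensor_param(array(0, channels))
  )
  conv7 <- nn_conv2d(2L, 1L, spatial_kernel, bias = TRUE)
  m <- new_module("cbam", params, children = list(conv_spatial = conv7),
                  meta = list(type = "cbam", out_ch = channels,
                              macs_per_px = 0))
  mlp <- function(d) {
    op_dense(op_relu(op_dense(d, m$params$W1, m$params$b1)),
             m$params$W2, m$params$b2)
  }
  m$channel_gate <- function(x) {
    op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_planemax(x))))
  }
  m$spatial_gate <- function(x, training = FALSE) {
    maps <- op_concat_c(list(op_cmean_c(x), op_cmax_c(x)))
    op_sigmoid(conv7$fwd(maps, training))
  }
  m$fwd <- function(x, training = FALSE) {
    if (order == "channel_first") {
      x <- op_scale_channels(x, m$channel_gate(x))
      op_scale_spatial(x, m$spatial_gate(x, training))
    } else {
      x <- op_scale_spatial(x, m$spatial_gate(x, training))
      op_scale_channels(x, m$channel_gate(x))
    }
  }
  m
}

#' CBAM channel-attention coefficients
#' @param block module from [nn_cbam()]
#' @param x feature map array
#' @return matrix `(C, N)` with entries strictly in (0, 1)
#' @export
cbam_channel_attention <- function(block, x) {
  as_value(block$channel_gate(tensor_const(as_featuremap(x))))
}

#' CBAM spatial-attention coefficients
#' @param block module from [nn_cbam()]
#' @param x feature map array
#' @return array `(H, W, 1, N)` with entries strictly in (0, 1)
#' @export
cbam_spatial_attention <- function(block, x) {
  x <- as_featuremap(x)
  if (dim(x)[1] < 1 || dim(x)[2] < 1) stop("spatial dims must be >= 1")
  as_value(block$spatial_gate(tensor_const(x)))
}

#' Apply a CBAM block to a feature map
#' @param block module from [nn_cbam()]
#' @param x feature map array `(H, W, C, N)`
#' @return array of the same shape
#' @export
cbam_forward <- function(block, x) block_forward(block, x)

#' Squeeze-and-excitation (SE) channel gate
#'
#' The classic channel-attention alternative to ECA: a bottleneck MLP on
#' the global-average-pooled descriptor, `sigmoid(W2 ReLU(W1 GAP(x)))`,
#' scaling each channel.  Provided as a drop-in comparison block for
#' attention ablations; it is not part of the default architecture.
#'
#' @param channels input channel count
#' @param reduction bottleneck reduction ratio
#' @export
nn_se <- function(channels, reduction = 16) {
  hid <- max(1L, channels %/% reduction)
  params <- list(
    W1 = tensor_param(init_xavier(c(hid, channels), channels, hid)),
    b1 = tensor_param(array(0, hid)),
    W2 = tensor_param(init_xavier(c(channels, hid), hid, channels)),
    b2 = tensor_param(array(0, channels))
  )
  m <- new_module("se", params,
                  meta = list(type = "se", out_ch = channels))
  m$fwd <- function(x, training = FALSE) {
    d <- op_relu(op_dense(op_gap(x), m$params$W1, m$params$b1))
    op_scale_channels(x, op_sigmoid(op_dense(d, m$params$W2, m$params$b2)))
  }
  m
}
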