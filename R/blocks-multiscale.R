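# ---------------------------------------------------------------------------
# Multi-scale context: atrous spatial pyramid pooling and its CBAM-refined
# bottleneck variant.
# ---------------------------------------------------------------------------

#' Atrous spatial pyramid pooling (ASPP) block
#'
#' Parallel 3x3 convolutions with the given dilation rates (default
#' `c(1, 2, 4, 8)`), each with "same" padding equal to its rate, are applied
#' to the input, concatenated along channels and fused by a 1x1 convolution.
#' Branch and fusion convolutions carry batch normalisation and ReLU
#' (`norm_act = FALSE` turns both off, leaving a purely linear operator used
#' by the superposition tests).  An optional image-level global-pooling
#' branch can be enabled; the default pyramid has only the dilated branches.
#'
#' @param in_ch input channels
#' @param branch_ch channels per branch; default `max(1, in_ch %/% 4)` so the
#'   concatenation returns to roughly `in_ch`
#' @param out_ch fused output channels; default `in_ch`
#' @param rates strictly increasing positive dilation rates
#' @param norm_act apply batch norm + ReLU after each convolution
#' @param global_branch add the image-pooling branch
#' @export
nn_aspp <- function(in_ch, branch_ch = NULL, out_ch = NULL,
                    rates = c(1L, 2L, 4L, 8L), norm_act = TRUE,
                    global_branch = FALSE) {
  if (!length(rates) || any(rates < 1) || any(diff(rates) <= 0)) {
    stop("rates must be non-empty, positive and strictly increasing")
  }
  branch_ch <- branch_ch %||% max(1L, in_ch %/% 4L)
  out_ch <- out_ch %||% in_ch
  mk_unit <- function(k, dil) {
    if (norm_act) {
      nn_conv_bn_relu(in_ch, branch_ch, k, pad = dil * (k - 1L) %/% 2L,
                      dil = dil)
    } else {
      nn_conv2d(in_ch, branch_ch, k, pad = dil * (k - 1L) %/% 2L, dil = dil,
                bias = FALSE)
    }
  }
  branches <- lapply(rates, function(r) mk_unit(3L, as.integer(r)))
  names(branches) <- sprintf("rate%d", rates)
  n_branch <- length(rates) + as.integer(global_branch)
  children <- branches
  if (global_branch) {
    children$global_conv <- if (norm_act) {
      nn_conv_bn_relu(in_ch, branch_ch, 1L)
    } else {
      nn_conv2d(in_ch, branch_ch, 1L, bias = FALSE)
    }
  }
  children$fuse <- if (norm_act) {
    nn_conv_bn_relu(n_branch * branch_ch, out_ch, 1L)
  } else {
    nn_conv2d(n_branch * branch_ch, out_ch, 1L, bias = FALSE)
  }
  m <- new_module("aspp", children = children,
                  meta = list(type = "aspp", out_ch = out_ch, rates = rates))
  m$fwd <- function(x, training = FALSE) {
    outs <- lapply(branches, function(b) b$fwd(x, training))
    if (global_branch) {
      d <- dim(x$value)
      g <- op_reshape(op_gap(x), c(1L, 1L, d[3], d[4]))
      g <- m$children$global_conv$fwd(g, training)
      outs <- c(outs, list(op_broadcast_hw(
        op_reshape(g, c(dim(g$value)[3], d[4])), d[1], d[2])))
    }
    m$children$fuse$fwd(op_concat_c(outs), training)
  }
  m
}

#' Apply an ASPP block to a feature map
#' @param block module from [nn_aspp()]
#' @param x feature map array `(H, W, C, N)`
#' @return array `(H, W, out_ch, N)`; spatial dims preserved
#' @export
aspp_forward <- function(block, x) block_forward(block, x)

#' CBAM-refined ASPP bottleneck block
#'
#' Composition `cbam(aspp(x))`: the pyramid gathers multi-scale context and
#' the attention module reweights its fused channels and positions before
#' decoding.
#'
#' @inheritParams nn_aspp
#' @param reduction CBAM MLP reduction ratio
#' @param order CBAM gate order; see [nn_cbam()]
#' @export
nn_cbam_aspp <- function(in_ch, branch_ch = NULL, out_ch = NULL,
                         rates = c(1L, 2L, 4L, 8L), reduction = 16,
                         order = "channel_first", norm_act = TRUE,
                         global_branch = FALSE) {
  out_ch <- out_ch %||% in_ch
  aspp <- nn_aspp(in_ch, branch_ch, out_ch, rates, norm_act, global_branch)
  cbam <- nn_cbam(out_ch, reduction, order = order)
  m <- new_module("cbam_aspp", children = list(aspp = aspp, cbam = cbam),
                  meta = list(type = "cbam_aspp", out_ch = out_ch))
  m$fwd <- function(x, training = FALSE) {
    cbam$fwd(aspp$fwd(x, training), training)
  }
  m
}

#' Apply a CBAM-ASPP block to a feature map
#' @param block module from [nn_cbam_aspp()]
#' @param x feature map array
#' @return array `(H, W, out_ch, N)`
#' @export
cbam_aspp_forward <- function(block, x) block_forward(block, x)
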