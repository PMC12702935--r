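# ---------------------------------------------------------------------------
# Depthwise-separable convolution and the analytic multiply-accumulate
# cost model used by the "inspect" and "ablate" reports.
# ---------------------------------------------------------------------------

#' Convolution cost-model descriptor
#'
#' Bundles the quantities entering the stride-1, same-padding cost model:
#' kernel size `Dk`, input channels `M`, output channels `N` and the square
#' spatial size `Df` shared by input and output maps.
#'
#' @param Dk odd positive kernel size
#' @param M,N input/output channel counts
#' @param Df spatial side length
#' @return an object of class `conv_spec`
#' @export
conv_spec <- function(Dk, M, N, Df) {
  vals <- c(Dk = Dk, M = M, N = N, Df = Df)
  if (any(vals < 1) || any(vals != floor(vals))) {
    stop("all conv_spec fields must be positive integers")
  }
  structure(as.list(vals), class = "conv_spec")
}

#' Multiply-accumulate count of a standard convolution
#'
#' `Dk^2 * M * N * Df^2` for a stride-1, same-padding layer.  One MAC is one
#' multiply plus one add; totals are reported as MACs throughout the package
#' to avoid the factor-2 FLOP ambiguity.
#'
#' @param spec a [conv_spec()]
#' @return non-negative count
#' @examples
#' conv_cost_standard(conv_spec(3, 16, 32, 8))  # 294912
#' @export
conv_cost_standard <- function(spec) {
  with(spec, Dk * Dk * M * N * Df * Df)
}

#' Multiply-accumulate count of a depthwise-separable convolution
#'
#' Depthwise stage `Dk^2 * M * Df^2` plus pointwise stage `M * N * Df^2`.
#'
#' @param spec a [conv_spec()]
#' @return non-negative count
#' @examples
#' conv_cost_dsc(conv_spec(3, 16, 32, 8))  # 41984
#' @export
conv_cost_dsc <- function(spec) {
  with(spec, Dk * Dk * M * Df * Df + M * N * Df * Df)
}

#' Cost ratio of separable to standard convolution
#'
#' Closed form `1/N + 1/Dk^2`, independent of `M` and `Df`.  The separable
#' factorisation is cheaper whenever `Dk >= 2` and `N >= 2`.
#'
#' @param spec a [conv_spec()]; only `N` and `Dk` are used
#' @return positive real
#' @export
cost_ratio <- function(spec) {
  with(spec, 1 / N + 1 / (Dk * Dk))
}

#' Generalised MAC count for strided convolutions
#'
#' The printed cost model assumes stride 1 and equal input/output sizes;
#' strided layers are counted with the output size `Ho x Wo`, reported
#' separately from the analytic model.
#' @param k kernel size
#' @param in_ch,out_ch channels
#' @param out_hw output spatial size (vector of 2 or scalar)
#' @param groups convolution groups
#' @return non-negative count
#' @export
conv_macs <- function(k, in_ch, out_ch, out_hw, groups = 1L) {
  if (length(out_hw) == 1L) out_hw <- c(out_hw, out_hw)
  k * k * (in_ch / groups) * out_ch * out_hw[1] * out_hw[2]
}

#' Depthwise-separable convolution layer
#'
#' A `k x k` per-channel (grouped) spatial convolution followed by a 1x1
#' pointwise convolution mixing channels.  Both stages are bias-free by
#' default (the decoder follows each with batch normalisation).  The
#' `depth_groups` knob generalises the spatial stage between ordinary
#' convolution (`1`) and full depthwise (`in_ch`, default).
#'
#' @param in_ch,out_ch channel counts
#' @param k spatial kernel size
#' @param stride,pad stride and padding of the spatial stage
#' @param depth_groups groups of the spatial stage; must divide `in_ch`
#' @param bias add a bias to the pointwise stage
#' @export
nn_dsc_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = NULL,
                        depth_groups = NULL, bias = FALSE) {
  depth_groups <- depth_groups %||% in_ch
  if (in_ch %% depth_groups != 0) stop("depth_groups must divide in_ch")
  dw <- nn_conv2d(in_ch, in_ch, k, stride = stride, pad = pad,
                  groups = depth_groups, bias = FALSE)
  pw <- nn_conv2d(in_ch, out_ch, 1L, bias = bias)
  m <- new_module("dsc_conv", children = list(depthwise = dw, pointwise = pw),
                  meta = list(type = "dsc_conv", in_ch = in_ch,
                              out_ch = out_ch, k = k))
  m$fwd <- function(x, training = FALSE) {
    pw$fwd(dw$fwd(x, training), training)
  }
  m
}

#' Apply a depthwise-separable convolution block
#'
#' Exactly equivalent to a standard convolution whose kernel is the rank-1
#' separable product `K[n, m, , ] = P[n, m] * D[m, , ]` of the pointwise and
#' depthwise kernels (when `depth_groups = in_ch`).
#'
#' @param block module from [nn_dsc_conv()]
#' @param x feature map array `(H, W, C, N)`
#' @return array `(H', W', out_ch, N)`
#' @export
dsc_forward <- function(block, x) block_forward(block, x)
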