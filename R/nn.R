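# ---------------------------------------------------------------------------
# Module system: a module owns named parameter tensors, named child modules,
# optional buffers (running statistics) and a forward closure.
# ---------------------------------------------------------------------------

new_module <- function(kind, params = list(), children = list(),
                       fwd = NULL, meta = list()) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- params
  m$children <- children
  m$meta <- meta
  m$fwd <- fwd
  class(m) <- c(paste0("hs_", kind), "hs_module")
  m
}

#' Collect all learnable parameter tensors of a module tree
#' @param m a module (or model)
#' @param prefix internal path prefix
#' @return named list of parameter tensors, names giving the module path
#' @export
module_params <- function(m, prefix = "") {
  if (inherits(m, "hs_model")) m <- m$net
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children)) {
    out <- c(out, module_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

module_buffers <- function(m, prefix = "") {
  if (inherits(m, "hs_model")) m <- m$net
  out <- list()
  if (!is.null(m$buffers)) out[[paste0(prefix, "<buf>")]] <- m$buffers
  for (nm in names(m$children)) {
    out <- c(out, module_buffers(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count learnable scalars in a block, module or model
#'
#' Sums the element counts of every learnable array (convolution kernels,
#' biases, normalisation scales/shifts, attention projections).
#'
#' @param block a module created by one of the `nn_*` constructors, or a
#'   model from [build_model()]
#' @return non-negative integer
#' @examples
#' count_parameters(nn_conv2d(16, 32, 3, bias = FALSE))  # 9*16*32 = 4608
#' count_parameters(nn_dsc_conv(16, 32, 3))              # 9*16 + 16*32 = 656
#' @export
count_parameters <- function(block) {
  ps <- module_params(block)
  if (!length(ps)) return(0L)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

forward_module <- function(m, x, training = FALSE) m$fwd(x, training)

#' Run a block on a plain feature-map array
#'
#' Convenience wrapper that wraps `x` as a constant tensor, runs the block's
#' forward pass and returns the resulting array.  Feature maps use the
#' `(H, W, C, N)` layout.
#'
#' @param block an `nn_*` module
#' @param x numeric array `(H, W, C, N)`
#' @param training logical; use batch statistics and dropout if `TRUE`
#' @return numeric array
#' @export
block_forward <- function(block, x, training = FALSE) {
  as_value(block$fwd(tensor_const(as_featuremap(x)), training))
}

# Accept (H,W), (H,W,C) or (H,W,C,N) input and return (H,W,C,N).
as_featuremap <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("feature map must have 2-4 dimensions")
  x
}

# ---------------------------------------------------------------------------
# Initialisers (consume the current RNG stream; callers seed once per model)
# ---------------------------------------------------------------------------

init_kaiming <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

init_xavier <- function(dims, fan_in, fan_out) {
  bound <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -bound, bound), dims)
}

# ---------------------------------------------------------------------------
# Basic layers
# ---------------------------------------------------------------------------

#' 2-D convolution layer
#'
#' @param in_ch,out_ch channel counts
#' @param k odd kernel size
#' @param stride,pad,dil,groups usual convolution hyperparameters; `pad`
#'   defaults to "same" padding `dil * (k - 1) / 2`
#' @param bias include an additive bias
#' @export
nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, dil = 1L,
                      groups = 1L, bias = TRUE) {
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop("channel counts must be divisible by groups")
  }
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  fan_in <- k * k * in_ch / groups
  params <- list(w = tensor_param(init_kaiming(c(k, k, in_ch / groups, out_ch),
                                               fan_in)))
  if (bias) {
    bb <- 1 / sqrt(fan_in)
    params$b <- tensor_param(array(stats::runif(out_ch, -bb, bb), out_ch))
  }
  m <- new_module("conv2d", params,
                  meta = list(type = "conv2d", in_ch = in_ch, out_ch = out_ch,
                              k = k, stride = stride, groups = groups,
                              macs_per_px = k * k * (in_ch / groups) * out_ch))
  m$fwd <- function(x, training = FALSE) {
    out <- op_conv2d(x, m$params$w, m$params$b, stride, pad, dil, groups)
    m$meta$last_out_hw <- dim(out$value)[1:2]
    out
  }
  m
}

op_bn2d <- function(x, gamma, beta, buffers, training,
                    momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gv <- gamma$value; bv <- beta$value
  hw <- H * W
  # per-channel reductions without copies: colSums over (H,W) gives (C,N),
  # then rowSums pools the batch
  csum <- function(a) rowSums(matrix(colSums(a, dims = 2L), C, N))
  if (training) {
    nobs <- hw * N
    mu <- csum(xv) / nobs
    va <- csum(xv * xv) / nobs - mu^2
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var +
      momentum * va * nobs / max(1, nobs - 1)
    invsd <- 1 / sqrt(va + eps)
    xhat <- (xv - rep(mu, each = hw)) * rep(invsd, each = hw)
    v <- xhat * rep(gv, each = hw) + rep(bv, each = hw)
    new_tensor(v, list(x, gamma, beta), function(g) {
      dgamma <- csum(g * xhat)
      dbeta <- csum(g)
      dxhat <- g * rep(gv, each = hw)
      dx <- (dxhat - rep(csum(dxhat) / nobs, each = hw) -
               xhat * rep(csum(dxhat * xhat) / nobs, each = hw)) *
        rep(invsd, each = hw)
      list(dx, dgamma, dbeta)
    })
  } else {
    invsd <- 1 / sqrt(buffers$var + eps)
    scale <- gv * invsd
    shift <- bv - buffers$mean * scale
    srep <- rep(scale, each = hw)
    v <- xv * srep + rep(shift, each = hw)
    mu <- buffers$mean
    new_tensor(v, list(x, gamma, beta), function(g) {
      xhat <- (xv - rep(mu, each = hw)) * rep(invsd, each = hw)
      list(g * srep, csum(g * xhat), csum(g))
    })
  }
}

#' Batch normalisation over channels of an (H,W,C,N) map
#' @param ch channel count
#' @param momentum running-statistics update rate
#' @export
nn_batchnorm2d <- function(ch, momentum = 0.1) {
  params <- list(gamma = tensor_param(array(1, ch)),
                 beta = tensor_param(array(0, ch)))
  m <- new_module("batchnorm2d", params,
                  meta = list(type = "batchnorm", out_ch = ch))
  m$buffers <- new.env(parent = emptyenv())
  m$buffers$mean <- numeric(ch)
  m$buffers$var <- rep(1, ch)
  m$fwd <- function(x, training = FALSE) {
    op_bn2d(x, m$params$gamma, m$params$beta, m$buffers, training, momentum)
  }
  m
}

nn_seq <- function(mods) {
  names(mods) <- sprintf("m%02d", seq_along(mods))
  m <- new_module("seq", children = mods)
  m$fwd <- function(x, training = FALSE) {
    for (ch in m$children) x <- ch$fwd(x, training)
    x
  }
  m
}

# conv -> batch norm -> ReLU, the standard encoder/decoder unit
nn_conv_bn_relu <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = NULL,
                            dil = 1L, groups = 1L) {
  conv <- nn_conv2d(in_ch, out_ch, k, stride, pad, dil, groups, bias = FALSE)
  bn <- nn_batchnorm2d(out_ch)
  m <- new_module("conv_bn_relu", children = list(conv = conv, bn = bn),
                  meta = list(type = "conv_bn_relu"))
  m$fwd <- function(x, training = FALSE) {
    op_relu(bn$fwd(conv$fwd(x, training), training))
  }
  m
}
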