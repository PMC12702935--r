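# ---------------------------------------------------------------------------
# Transformer primitives: scaled dot-product attention, multi-head
# attention, the token MLP, sinusoidal positional encoding and the encoder
# stack.  The plain-matrix functions are the reference API (and the oracle
# side of the dual-route tests); nn_* modules are the trainable path.
# ---------------------------------------------------------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, rows of the softmax summing to 1.
#'
#' @param Q query matrix `(n_q, d_k)`
#' @param K key matrix `(n_kv, d_k)`
#' @param V value matrix `(n_kv, d_v)`
#' @return matrix `(n_q, d_v)`
#' @examples
#' # a single key/value token returns V for any query
#' scaled_dot_attention(matrix(rnorm(3), 3, 1), matrix(0), matrix(2))
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share the token count")
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(ncol(K)))
  A %*% V
}

#' Multi-head self-attention on a token matrix
#'
#' Projects `x` with per-model matrices `Wq`, `Wk`, `Wv` (dim x dim), splits
#' the projections into `h` equal head slices, runs scaled dot-product
#' attention independently per head, concatenates the head outputs and
#' projects with `Wo`.
#'
#' @param x token matrix `(n_tokens, dim)`
#' @param p list with projection matrices `Wq`, `Wk`, `Wv`, `Wo`, each
#'   `(dim, dim)`
#' @param h number of heads; must divide `dim`
#' @return matrix `(n_tokens, dim)`
#' @export
msa_forward <- function(x, p, h = 1L) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (D %% h != 0) stop("dim must be divisible by the number of heads")
  dh <- D %/% h
  q <- x %*% p$Wq; k <- x %*% p$Wk; v <- x %*% p$Wv
  out <- matrix(0, nrow(x), D)
  for (i in seq_len(h)) {
    idx <- (i - 1L) * dh + seq_len(dh)
    out[, idx] <- scaled_dot_attention(q[, idx, drop = FALSE],
                                       k[, idx, drop = FALSE],
                                       v[, idx, drop = FALSE])
  }
  out %*% p$Wo
}

#' Position-wise MLP on a token matrix
#'
#' `max(0, x W1 + b1) W2 + b2`, the two affine maps with a ReLU between.
#'
#' @param x token matrix `(n_tokens, dim)`
#' @param p list with `W1 (dim, hidden)`, `b1 (hidden)`, `W2 (hidden, dim)`,
#'   `b2 (dim)`
#' @return matrix `(n_tokens, dim)`
#' @export
mlp_forward <- function(x, p) {
  x <- as.matrix(x)
  h <- pmax(sweep(x %*% p$W1, 2L, p$b1, "+"), 0)
  sweep(h %*% p$W2, 2L, p$b2, "+")
}

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d))` with 0-based `pos` and `i`.
#'
#' @param n_pos number of positions
#' @param d even embedding dimension
#' @return matrix `(n_pos, d)` with entries in `[-1, 1]`
#' @export
sinusoidal_pe <- function(n_pos, d) {
  if (d %% 2 != 0) stop("embedding dimension must be even")
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d %/% 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n_pos, d)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

# --- trainable modules ------------------------------------------------------

nn_msa <- function(dim, heads) {
  if (dim %% heads != 0) stop("dim must be divisible by the number of heads")
  p <- list(
    Wq = tensor_param(init_xavier(c(dim, dim), dim, dim)),
    Wk = tensor_param(init_xavier(c(dim, dim), dim, dim)),
    Wv = tensor_param(init_xavier(c(dim, dim), dim, dim)),
    Wo = tensor_param(init_xavier(c(dim, dim), dim, dim))
  )
  m <- new_module("msa", p, meta = list(type = "msa", dim = dim,
                                        heads = heads))
  m$fwd <- function(x, training = FALSE) {
    m$meta$last_tokens <- dim(x$value)[1]
    op_linear_tokens(
      op_mha(op_linear_tokens(x, m$params$Wq),
             op_linear_tokens(x, m$params$Wk),
             op_linear_tokens(x, m$params$Wv), heads),
      m$params$Wo)
  }
  m
}

nn_mlp_tokens <- function(dim, hidden) {
  p <- list(
    W1 = tensor_param(init_xavier(c(dim, hidden), dim, hidden)),
    b1 = tensor_param(array(0, hidden)),
    W2 = tensor_param(init_xavier(c(hidden, dim), hidden, dim)),
    b2 = tensor_param(array(0, dim))
  )
  m <- new_module("mlp_tokens", p,
                  meta = list(type = "mlp", dim = dim, hidden = hidden))
  m$fwd <- function(x, training = FALSE) {
    m$meta$last_tokens <- dim(x$value)[1]
    op_linear_tokens(op_relu(op_linear_tokens(x, m$params$W1, m$params$b1)),
                     m$params$W2, m$params$b2)
  }
  m
}

nn_layernorm_tokens <- function(dim) {
  p <- list(gamma = tensor_param(array(1, dim)),
            beta = tensor_param(array(0, dim)))
  m <- new_module("layernorm", p, meta = list(type = "layernorm", dim = dim))
  m$fwd <- function(x, training = FALSE) {
    op_layernorm_tokens(x, m$params$gamma, m$params$beta)
  }
  m
}

nn_encoder_layer <- function(dim, heads, mlp_dim, dropout = 0,
                             prenorm = TRUE) {
  ch <- list(ln1 = nn_layernorm_tokens(dim), msa = nn_msa(dim, heads),
             ln2 = nn_layernorm_tokens(dim), mlp = nn_mlp_tokens(dim, mlp_dim))
  m <- new_module("encoder_layer", children = ch,
                  meta = list(type = "encoder_layer", dim = dim))
  m$fwd <- function(x, training = FALSE) {
    if (prenorm) {
      x <- op_add(x, op_dropout(ch$msa$fwd(ch$ln1$fwd(x, training), training),
                                dropout, training))
      op_add(x, op_dropout(ch$mlp$fwd(ch$ln2$fwd(x, training), training),
                           dropout, training))
    } else {
      x <- ch$ln1$fwd(op_add(x, op_dropout(ch$msa$fwd(x, training), dropout,
                                           training)), training)
      ch$ln2$fwd(op_add(x, op_dropout(ch$mlp$fwd(x, training), dropout,
                                      training)), training)
    }
  }
  m
}

#' Transformer encoder stack
#'
#' `n_layers` repetitions of (layer norm, multi-head self-attention,
#' residual add, layer norm, MLP, residual add) in the pre-norm arrangement
#' by default.  Positional encoding must already be added to the input
#' tokens; a 0-layer stack is the identity.
#'
#' @param dim embedding dimension, divisible by `heads`
#' @param heads attention heads
#' @param mlp_dim hidden width of the token MLP
#' @param n_layers number of encoder layers
#' @param dropout dropout rate on the residual branches (0 disables)
#' @param prenorm pre-norm (default) vs post-norm arrangement
#' @export
nn_encoder_stack <- function(dim, heads, mlp_dim, n_layers = 12L,
                             dropout = 0, prenorm = TRUE) {
  layers <- lapply(seq_len(n_layers), function(i) {
    nn_encoder_layer(dim, heads, mlp_dim, dropout, prenorm)
  })
  names(layers) <- sprintf("layer%02d", seq_len(n_layers))
  m <- new_module("encoder_stack", children = layers,
                  meta = list(type = "encoder_stack", dim = dim,
                              n_layers = n_layers))
  m$fwd <- function(x, training = FALSE) {
    for (i in seq_len(n_layers)) x <- m$children[[i]]$fwd(x, training)
    x
  }
  m
}

#' Run an encoder stack on a plain token array
#' @param block module from [nn_encoder_stack()]
#' @param x token array `(n_tokens, dim, N)` or matrix `(n_tokens, dim)`
#' @return array of the same shape
#' @export
encoder_stack_forward <- function(block, x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  out <- as_value(block$fwd(tensor_const(x), FALSE))
  if (length(d) == 2L) dim(out) <- d
  out
}
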