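# ---------------------------------------------------------------------------
# Differentiable tensor operations.
#
# Feature maps are (H, W, C, N) arrays, token sequences (T, D, N), channel
# descriptors (C, N).  Every op computes its value eagerly and registers a
# backward closure mapping the output gradient to per-parent gradients.
# ---------------------------------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L,
                      groups = 1L) {
  xv <- x$value; wv <- w$value
  v <- cpp_conv2d_fw(xv, wv, if (is.null(b)) NULL else b$value,
                     stride, pad, dil, groups)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  need_gx <- x$needs
  new_tensor(v, parents, function(g) {
    r <- cpp_conv2d_bw(xv, wv, g, stride, pad, dil, groups,
                       need_gx, !is.null(b))
    if (is.null(b)) list(r$gx, r$gw) else list(r$gx, r$gw, r$gb)
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  v <- x$value * mask
  new_tensor(v, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  v <- array(stats::plogis(x$value), dim(x$value))
  new_tensor(v, list(x), function(g) list(g * v * (1 - v)))
}

op_add <- function(x, y) {
  new_tensor(x$value + y$value, list(x, y), function(g) list(g, g))
}

op_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- array((stats::runif(length(x$value)) >= p) / (1 - p), dim(x$value))
  new_tensor(x$value * keep, list(x), function(g) list(g * keep))
}

# x: (H,W,C,N) scaled per-channel by w: (C,N)
op_scale_channels <- function(x, w) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); hw <- d[1] * d[2]
  wrep <- rep(as.vector(wv), each = hw)
  v <- xv * wrep
  new_tensor(v, list(x, w), function(g) {
    dw <- array(colSums(array(g * xv, c(hw, d[3] * d[4]))), dim(wv))
    list(g * wrep, dw)
  })
}

# x: (H,W,C,N) scaled per-position by s: (H,W,1,N)
op_scale_spatial <- function(x, s) {
  xv <- x$value; sv <- s$value
  d <- dim(xv); C <- d[3]
  se <- sv[, , rep(1L, C), , drop = FALSE]
  v <- xv * se
  new_tensor(v, list(x, s), function(g) {
    m <- array(g * xv, c(d[1] * d[2], C, d[4]))
    ds <- array(0, dim(sv))
    for (n in seq_len(d[4])) ds[, , 1L, n] <- rowSums(matrix(m[, , n], ncol = C))
    list(g * se, ds)
  })
}

op_concat_c <- function(xs) {
  d <- dim(xs[[1]]$value)
  cs <- vapply(xs, function(t) dim(t$value)[3], numeric(1))
  v <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (t in xs) {
    ci <- dim(t$value)[3]
    v[, , at + seq_len(ci), ] <- t$value
    at <- at + ci
  }
  ends <- cumsum(cs)
  starts <- ends - cs + 1
  new_tensor(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , starts[i]:ends[i], , drop = FALSE])
  })
}

# Global average pool (H,W,C,N) -> (C,N)
op_gap <- function(x) {
  xv <- x$value; d <- dim(xv); hw <- d[1] * d[2]
  v <- matrix(colMeans(xv, dims = 2L), d[3], d[4])
  new_tensor(v, list(x), function(g) {
    list(array(rep(as.vector(g) / hw, each = hw), d))
  })
}

# Global max pool (H,W,C,N) -> (C,N)
op_planemax <- function(x) {
  xv <- x$value; d <- dim(xv); hw <- d[1] * d[2]
  m <- array(xv, c(hw, d[3] * d[4]))
  idx <- max.col(t(m), ties.method = "first")
  v <- array(m[cbind(idx, seq_along(idx))], c(d[3], d[4]))
  new_tensor(v, list(x), function(g) {
    gx <- array(0, d)
    gx[idx + (seq_along(idx) - 1L) * hw] <- as.vector(g)
    list(gx)
  })
}

# Channel-wise mean map (H,W,C,N) -> (H,W,1,N)
op_cmean_c <- function(x) {
  xv <- x$value; d <- dim(xv); C <- d[3]
  m <- array(xv, c(d[1] * d[2], C, d[4]))
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) v[, , 1L, n] <- rowMeans(matrix(m[, , n], ncol = C))
  new_tensor(v, list(x), function(g) {
    list(g[, , rep(1L, C), , drop = FALSE] / C)
  })
}

# Channel-wise max map (H,W,C,N) -> (H,W,1,N)
op_cmax_c <- function(x) {
  xv <- x$value; d <- dim(xv); C <- d[3]; hw <- d[1] * d[2]
  m <- array(xv, c(hw, C, d[4]))
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  idxs <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    mm <- matrix(m[, , n], ncol = C)
    idxs[[n]] <- max.col(mm, ties.method = "first")
    v[, , 1L, n] <- mm[cbind(seq_len(hw), idxs[[n]])]
  }
  new_tensor(v, list(x), function(g) {
    gm <- array(0, c(hw, C, d[4]))
    for (n in seq_len(d[4])) {
      gm[cbind(seq_len(hw), idxs[[n]], n)] <- as.vector(g[, , 1L, n])
    }
    list(array(gm, d))
  })
}

op_maxpool2d <- function(x, k, stride, pad) {
  xv <- x$value
  r <- cpp_maxpool2d_fw(xv, k, stride, pad)
  new_tensor(r$out, list(x), function(g) {
    list(cpp_maxpool2d_bw(r$argmax, g, dim(xv)))
  })
}

# Interpolation matrix mapping n_in samples to n_out (bilinear, half-pixel
# centers, clamped at the borders).
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  fr <- src - i0
  lo <- pmin(pmax(i0, 0), n_in - 1) + 1
  hi <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  A[cbind(seq_len(n_out), lo)] <- A[cbind(seq_len(n_out), lo)] + (1 - fr)
  A[cbind(seq_len(n_out), hi)] <- A[cbind(seq_len(n_out), hi)] + fr
  A
}

# Per-axis bilinear interpolation stencils (half-pixel centers, clamped).
bilinear_idx <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  list(lo = as.integer(pmin(pmax(i0, 0), n_in - 1)),
       hi = as.integer(pmin(pmax(i0 + 1, 0), n_in - 1)),
       fr = src - i0)
}

# Bilinear x2 spatial upsampling (compiled separable interpolation).
op_upsample2x <- function(x, ri, ci) {
  xv <- x$value; d <- dim(xv)
  v <- cpp_upsample2x_fw(xv, ri$lo, ri$hi, ri$fr, ci$lo, ci$hi, ci$fr)
  new_tensor(v, list(x), function(g) {
    list(cpp_upsample2x_bw(g, d, ri$lo, ri$hi, ri$fr, ci$lo, ci$hi, ci$fr))
  })
}

# Broadcast a channel descriptor (C,N) over an H x W plane.
op_broadcast_hw <- function(x, H, W) {
  xv <- x$value; C <- dim(xv)[1]; N <- dim(xv)[2]
  v <- array(rep(as.vector(xv), each = H * W), c(H, W, C, N))
  new_tensor(v, list(x), function(g) {
    list(array(colSums(array(g, c(H * W, C * N))), c(C, N)))
  })
}

op_reshape <- function(x, newdim) {
  olddim <- dim(x$value)
  v <- x$value
  dim(v) <- newdim
  new_tensor(v, list(x), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

# Dense map on channel descriptors: x (Din,N), W (Dout,Din), b (Dout)
op_dense <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  v <- Wv %*% xv
  if (!is.null(b)) v <- v + as.vector(b$value)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  new_tensor(v, parents, function(g) {
    out <- list(crossprod(Wv, g), tcrossprod(g, xv))
    if (!is.null(b)) out[[3]] <- rowSums(g)
    out
  })
}

# Token-wise affine map: x (T,Din,N), W (Din,Dout), b (Dout)
op_linear_tokens <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  d <- dim(xv); TT <- d[1]; Din <- d[2]; N <- d[3]
  Dout <- ncol(Wv)
  xm <- array(aperm(xv, c(1, 3, 2)), c(TT * N, Din))
  vm <- xm %*% Wv
  if (!is.null(b)) vm <- sweep(vm, 2L, b$value, "+")
  v <- aperm(array(vm, c(TT, N, Dout)), c(1, 3, 2))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  new_tensor(v, parents, function(g) {
    gm <- array(aperm(g, c(1, 3, 2)), c(TT * N, Dout))
    dx <- aperm(array(gm %*% t(Wv), c(TT, N, Din)), c(1, 3, 2))
    out <- list(dx, crossprod(xm, gm))
    if (!is.null(b)) out[[3]] <- colSums(gm)
    out
  })
}

# Layer normalisation over the embedding axis of (T,D,N) tokens.
op_layernorm_tokens <- function(x, gamma, beta, eps = 1e-6) {
  xv <- x$value; gv <- gamma$value; bv <- beta$value
  d <- dim(xv); TT <- d[1]; D <- d[2]; N <- d[3]
  xm <- array(aperm(xv, c(1, 3, 2)), c(TT * N, D))
  mu <- rowMeans(xm)
  xc <- xm - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  ym <- sweep(xhat, 2L, gv, "*")
  ym <- sweep(ym, 2L, bv, "+")
  v <- aperm(array(ym, c(TT, N, D)), c(1, 3, 2))
  new_tensor(v, list(x, gamma, beta), function(g) {
    gm <- array(aperm(g, c(1, 3, 2)), c(TT * N, D))
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- sweep(gm, 2L, gv, "*")
    dxm <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / sd
    list(aperm(array(dxm, c(TT, N, D)), c(1, 3, 2)), dgamma, dbeta)
  })
}

softmax_rows <- function(S) {
  mx <- S[, 1L]
  for (j in seq_len(ncol(S))[-1L]) mx <- pmax(mx, S[, j])
  e <- exp(S - mx)
  e / rowSums(e)
}

# Multi-head scaled dot-product attention core on projected (T,D,N) tokens.
op_mha <- function(q, k, v, heads) {
  qv <- q$value; kv <- k$value; vv <- v$value
  d <- dim(qv); TT <- d[1]; D <- d[2]; N <- d[3]
  dh <- D %/% heads
  sc <- 1 / sqrt(dh)
  out <- array(0, d)
  cache <- vector("list", N * heads)
  ci <- 0L
  for (n in seq_len(N)) {
    for (h in seq_len(heads)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      Qh <- matrix(qv[, idx, n], TT, dh)
      Kh <- matrix(kv[, idx, n], TT, dh)
      Vh <- matrix(vv[, idx, n], TT, dh)
      A <- softmax_rows(tcrossprod(Qh, Kh) * sc)
      out[, idx, n] <- A %*% Vh
      ci <- ci + 1L
      cache[[ci]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh, idx = idx, n = n)
    }
  }
  new_tensor(out, list(q, k, v), function(g) {
    dq <- array(0, d); dk <- array(0, d); dv <- array(0, d)
    for (cc in cache) {
      gO <- matrix(g[, cc$idx, cc$n], TT, dh)
      dv[, cc$idx, cc$n] <- crossprod(cc$A, gO)
      dA <- tcrossprod(gO, cc$Vh)
      dS <- cc$A * (dA - rowSums(dA * cc$A))
      dq[, cc$idx, cc$n] <- dS %*% cc$Kh * sc
      dk[, cc$idx, cc$n] <- crossprod(dS, cc$Qh) * sc
    }
    list(dq, dk, dv)
  })
}

# Add a fixed (T,D) positional-encoding matrix (or a learnable one) to tokens.
op_add_pe <- function(x, pe) {
  xv <- x$value
  N <- dim(xv)[3]
  pev <- as_value(pe)
  v <- xv + as.vector(pev)
  if (is_tensor(pe)) {
    new_tensor(v, list(x, pe), function(g) {
      list(g, array(rowSums(array(g, c(length(pev), N))), dim(pev)))
    })
  } else {
    new_tensor(v, list(x), function(g) list(g))
  }
}

# ---------------------------------------------------------------------------
# Fused segmentation objective: softmax + (cross-entropy + soft Dice)/2.
# logits (H,W,M,N), labels (H,W,N) integer in [0, M).
# ---------------------------------------------------------------------------
op_seg_loss <- function(logits, labels, include_background = TRUE,
                        eps = 1e-5) {
  lv <- logits$value
  d <- dim(lv); P <- d[1] * d[2]; M <- d[3]; N <- d[4]
  lab <- array(as.integer(labels), c(P, N))
  if (any(lab < 0L) || any(lab >= M)) {
    stop("label values must lie in [0, num_classes)")
  }
  pm <- array(0, c(P, M, N))
  lv3 <- array(lv, c(P, M, N))
  ce_sum <- 0
  I <- numeric(M); PS <- numeric(M); YS <- numeric(M)
  for (n in seq_len(N)) {
    ln <- matrix(lv3[, , n], P, M)
    p <- softmax_rows(ln)
    pm[, , n] <- p
    truth <- cbind(seq_len(P), lab[, n] + 1L)
    ce_sum <- ce_sum - sum(log(pmax(p[truth], 1e-12)))
    for (c in seq_len(M)) {
      yc <- lab[, n] == (c - 1L)
      I[c] <- I[c] + sum(p[yc, c])
      PS[c] <- PS[c] + sum(p[, c])
      YS[c] <- YS[c] + sum(yc)
    }
  }
  npix <- P * N
  ce <- ce_sum / npix
  sel <- if (include_background) seq_len(M) else seq_len(M)[-1]
  U <- PS + YS
  dice_c <- 1 - (2 * I + eps) / (U + eps)
  dice <- mean(dice_c[sel])
  loss <- (ce + dice) / 2
  t <- new_tensor(loss, list(logits), function(g) {
    gs <- as.numeric(g)
    dz <- array(0, d)
    # d(dice)/dp per class, zero outside the selected set
    dp_c <- numeric(M)
    dp_c[sel] <- ((2 * I[sel] + eps)) / (U[sel] + eps)^2 / length(sel)
    dy_c <- numeric(M)
    dy_c[sel] <- -2 / (U[sel] + eps) / length(sel)
    for (n in seq_len(N)) {
      p <- matrix(pm[, , n], P, M)
      onehot <- matrix(0, P, M)
      onehot[cbind(seq_len(P), lab[, n] + 1L)] <- 1
      dz_ce <- (p - onehot) / npix
      # dL_dice/dp_ic = dp_c[c] + dy_c[c]*y_ic ; chain through softmax
      gp <- sweep(onehot, 2L, dy_c, "*")
      gp <- sweep(gp, 2L, dp_c, "+")
      dz_dice <- p * (gp - rowSums(gp * p))
      dz[, , , n] <- array((dz_ce + dz_dice) / 2, c(d[1], d[2], M))
    }
    list(dz * gs)
  })
  t$ce <- ce
  t$dice <- dice
  t$prob <- array(pm, c(d[1], d[2], M, N))
  t
}
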