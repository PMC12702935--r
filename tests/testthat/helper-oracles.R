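# Independent brute-force oracles.  These deliberately avoid the package's
# im2col/GEMM path: convolutions are computed by shift-and-add over kernel
# taps, attention/pooling reductions by explicit loops.

rand_map <- function(H, W, C, N = 1L) {
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}

# shift-and-add convolution, "same"-style arbitrary padding
naive_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L,
                       groups = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  Og <- Cout / groups
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(Hp, Wp, C, N))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  Ho <- (Hp - (dil * (kh - 1L) + 1L)) %/% stride + 1L
  Wo <- (Wp - (dil * (kw - 1L) + 1L)) %/% stride + 1L
  out <- array(0, c(Ho, Wo, Cout, N))
  rsel <- (seq_len(Ho) - 1L) * stride
  csel <- (seq_len(Wo) - 1L) * stride
  for (n in seq_len(N)) for (co in seq_len(Cout)) {
    g <- ceiling(co / Og)
    acc <- matrix(if (is.null(b)) 0 else b[co], Ho, Wo)
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (c in seq_len(Cg)) {
      acc <- acc + w[i, j, c, co] *
        xp[rsel + (i - 1L) * dil + 1L, csel + (j - 1L) * dil + 1L,
           (g - 1L) * Cg + c, n]
    }
    out[, , co, n] <- acc
  }
  out
}

naive_bn_eval <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[3])) {
    out[, , c, ] <- (x[, , c, ] - mean[c]) / sqrt(var[c] + eps) * gamma[c] +
      beta[c]
  }
  out
}

naive_sigmoid <- function(z) 1 / (1 + exp(-z))

# ECA oracle: loops over channels, explicit dot product per window
naive_eca <- function(block, x) {
  d <- dim(x); C <- d[3]; N <- d[4]
  w <- block$params$w$value
  k <- length(w)
  pad <- (k - 1) %/% 2
  out <- x
  for (n in seq_len(N)) {
    g <- numeric(C)
    for (c in seq_len(C)) g[c] <- mean(x[, , c, n])
    gp <- c(rep(0, pad), g, rep(0, pad))
    wt <- numeric(C)
    for (c in seq_len(C)) {
      s <- 0
      for (j in seq_len(k)) s <- s + w[j] * gp[c + j - 1]
      wt[c] <- naive_sigmoid(s)
    }
    for (c in seq_len(C)) out[, , c, n] <- x[, , c, n] * wt[c]
  }
  out
}

naive_cbam_channel <- function(block, x) {
  d <- dim(x); C <- d[3]; N <- d[4]
  W1 <- block$params$W1$value; b1 <- as.vector(block$params$b1$value)
  W2 <- block$params$W2$value; b2 <- as.vector(block$params$b2$value)
  mlp <- function(v) as.vector(W2 %*% pmax(as.vector(W1 %*% v) + b1, 0)) + b2
  out <- matrix(0, C, N)
  for (n in seq_len(N)) {
    avg <- numeric(C); mx <- numeric(C)
    for (c in seq_len(C)) {
      avg[c] <- mean(x[, , c, n])
      mx[c] <- max(x[, , c, n])
    }
    out[, n] <- naive_sigmoid(mlp(avg) + mlp(mx))
  }
  out
}

naive_cbam_spatial <- function(block, x) {
  d <- dim(x); C <- d[3]; N <- d[4]
  conv <- block$children$conv_spatial
  w <- conv$params$w$value; b <- as.vector(conv$params$b$value)
  maps <- array(0, c(d[1], d[2], 2L, N))
  for (n in seq_len(N)) for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    maps[r, cc, 1L, n] <- mean(x[r, cc, , n])
    maps[r, cc, 2L, n] <- max(x[r, cc, , n])
  }
  k <- dim(w)[1]
  naive_sigmoid(naive_conv(maps, w, b, pad = (k - 1L) %/% 2L))
}

naive_cbam <- function(block, x) {
  mc <- naive_cbam_channel(block, x)
  d <- dim(x)
  xp <- x
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    xp[, , c, n] <- x[, , c, n] * mc[c, n]
  }
  ms <- naive_cbam_spatial(block, xp)
  out <- xp
  for (c in seq_len(d[3])) out[, , c, ] <- xp[, , c, ] * ms[, , 1L, ]
  out
}

# ASPP oracle in eval mode (running statistics: mean 0, var 1 at init)
naive_conv_bn_relu <- function(unit, x, dil = 1L) {
  conv <- unit$children$conv; bn <- unit$children$bn
  w <- conv$params$w$value
  k <- dim(w)[1]
  y <- naive_conv(x, w, pad = dil * (k - 1L) %/% 2L, dil = dil)
  y <- naive_bn_eval(y, as.vector(bn$params$gamma$value),
                     as.vector(bn$params$beta$value),
                     bn$buffers$mean, bn$buffers$var)
  pmax(y, 0)
}

naive_aspp <- function(block, x, rates = c(1L, 2L, 4L, 8L)) {
  outs <- lapply(seq_along(rates), function(i) {
    naive_conv_bn_relu(block$children[[sprintf("rate%d", rates[i])]], x,
                       dil = rates[i])
  })
  cc <- array(0, c(dim(x)[1], dim(x)[2],
                   sum(vapply(outs, function(o) dim(o)[3], numeric(1))),
                   dim(x)[4]))
  at <- 0L
  for (o in outs) {
    cc[, , at + seq_len(dim(o)[3]), ] <- o
    at <- at + dim(o)[3]
  }
  naive_conv_bn_relu(block$children$fuse, cc, dil = 1L)
}

naive_cbam_aspp <- function(block, x, rates = c(1L, 2L, 4L, 8L)) {
  naive_cbam(block$children$cbam,
             naive_aspp(block$children$aspp, x, rates))
}

# rank-1 product kernel of a depthwise-separable block (full depthwise)
dsc_product_kernel <- function(block) {
  dw <- block$children$depthwise$params$w$value  # (k,k,1,M)
  pw <- block$children$pointwise$params$w$value  # (1,1,M,N)
  k <- dim(dw)[1]; M <- dim(dw)[4]; Nn <- dim(pw)[4]
  kk <- array(0, c(k, k, M, Nn))
  for (n in seq_len(Nn)) for (m in seq_len(M)) {
    kk[, , m, n] <- pw[1, 1, m, n] * dw[, , 1, m]
  }
  kk
}

# literal double-loop Hausdorff oracle on full point sets
hausdorff_loop <- function(A, B) {
  dmin <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(dmin(A, B), dmin(B, A))
}

rand_mask_points <- function(n_max = 200L, lim = 40L) {
  n <- sample.int(n_max, 1L)
  cbind(sample.int(lim, n, replace = TRUE), sample.int(lim, n, replace = TRUE))
}

set_params_zero <- function(block) {
  for (p in module_params(block)) p$value[] <- 0
  invisible(block)
}
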