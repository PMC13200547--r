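# Internal neural-network primitives for 1D signals.
#
# Tensors are numeric arrays with dim (channels, length, batch). 1D
# convolutions are evaluated as one matrix product per kernel tap, which for
# the default 1x1 kernels reduces to a single BLAS call per layer; the
# 1x1/stride-1 case takes a copy-free fast path. Backward passes are
# hand-derived; there is no autodiff.

# same-padding 1D convolution; W has dim (C_out, C_in, k), k odd, no bias
conv_fwd <- function(x, W, stride = 1L) {
  d <- dim(x); C_in <- d[1L]; L <- d[2L]; B <- d[3L]
  k <- dim(W)[3L]; C_out <- dim(W)[1L]
  if (k == 1L && stride == 1L) {
    xm <- x; dim(xm) <- c(C_in, L * B)
    y <- matrix(W, C_out, C_in) %*% xm
    dim(y) <- c(C_out, L, B)
    return(list(y = y,
                cache = list(fast = TRUE, x = x, L = L, B = B, C_in = C_in)))
  }
  pad <- (k - 1L) %/% 2L
  L_out <- (L + 2L * pad - k) %/% stride + 1L
  if (L_out < 1L) stop("input length ", L, " too short for kernel ", k,
                       " stride ", stride)
  if (pad > 0L) {
    xp <- array(0, dim = c(C_in, L + 2L * pad, B))
    xp[, pad + seq_len(L), ] <- x
  } else xp <- x
  ymat <- matrix(0, C_out, L_out * B)
  base <- (seq_len(L_out) - 1L) * stride
  for (j in seq_len(k)) {
    xs <- xp[, base + j, , drop = FALSE]
    dim(xs) <- c(C_in, L_out * B)
    ymat <- ymat + matrix(W[, , j], C_out, C_in) %*% xs
  }
  dim(ymat) <- c(C_out, L_out, B)
  list(y = ymat, cache = list(fast = FALSE, xp = xp, L = L, pad = pad,
                              stride = stride, k = k, L_out = L_out, B = B,
                              C_in = C_in))
}

conv_bwd <- function(dy, W, cache) {
  C_out <- dim(W)[1L]; C_in <- cache$C_in
  if (isTRUE(cache$fast)) {
    L <- cache$L; B <- cache$B
    dym <- dy; dim(dym) <- c(C_out, L * B)
    xm <- cache$x; dim(xm) <- c(C_in, L * B)
    dW <- tcrossprod(dym, xm)
    dim(dW) <- c(C_out, C_in, 1L)
    dx <- crossprod(matrix(W, C_out, C_in), dym)
    dim(dx) <- c(C_in, L, B)
    return(list(dx = dx, dW = dW))
  }
  L_out <- cache$L_out; B <- cache$B; k <- cache$k
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(cache$xp))
  dym <- dy; dim(dym) <- c(C_out, L_out * B)
  base <- (seq_len(L_out) - 1L) * cache$stride
  for (j in seq_len(k)) {
    xs <- cache$xp[, base + j, , drop = FALSE]
    dim(xs) <- c(C_in, L_out * B)
    dW[, , j] <- tcrossprod(dym, xs)
    dxs <- crossprod(matrix(W[, , j], C_out, C_in), dym)
    dim(dxs) <- c(C_in, L_out, B)
    dxp[, base + j, ] <- dxp[, base + j, , drop = FALSE] + dxs
  }
  dx <- if (cache$pad > 0L) dxp[, cache$pad + seq_len(cache$L), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW)
}

# batch normalization over (length, batch) per channel; the training path
# runs through the fused compiled kernels
bn_fwd <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]; N <- d[2L] * d[3L]
  xm <- x; dim(xm) <- c(C, N)
  if (training) {
    f <- bn_forward_cpp(xm, gamma, beta, eps)
    run$mean <- (1 - momentum) * run$mean + momentum * f$mu
    run$var <- (1 - momentum) * run$var + momentum * f$var
    y <- f$y
    dim(y) <- d
    return(list(y = y, run = run,
                cache = list(xhat = f$xhat, invstd = f$invstd,
                             gamma = gamma, d = d)))
  }
  invstd <- 1 / sqrt(run$var + eps)
  y <- gamma * ((xm - run$mean) * invstd) + beta
  dim(y) <- d
  list(y = y, run = run, cache = NULL)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  dym <- dy; dim(dym) <- c(d[1L], d[2L] * d[3L])
  b <- bn_backward_cpp(dym, cache$xhat, cache$invstd, cache$gamma)
  dx <- b$dx
  dim(dx) <- d
  list(dx = dx, dgamma = b$dgamma, dbeta = b$dbeta)
}

relu_fwd <- function(x) {
  y <- relu_forward_cpp(x)
  dim(y) <- dim(x)
  list(y = y, cache = y)
}

relu_bwd <- function(dy, y) {
  dx <- relu_backward_cpp(dy, y)
  dim(dx) <- dim(dy)
  dx
}

# adaptive average pooling to length 1: (C, L, B) -> (C, B)
pool_fwd <- function(x) {
  d <- dim(x)
  y <- .colMeans(aperm(x, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  dim(y) <- c(d[1L], d[3L])
  list(y = y, cache = d)
}

pool_bwd <- function(dy, d) {
  aperm(array(dy / d[2L], dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

# He-style initialization helpers (seeded by the caller)
init_conv <- function(C_out, C_in, k) {
  array(stats::rnorm(C_out * C_in * k, sd = sqrt(2 / (C_in * k))),
        dim = c(C_out, C_in, k))
}
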