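# Minimal CNN engine: stride-1 "same" convolutions via im2col, 2x2 max
# pooling, global average pooling, dense layers, softmax/sigmoid heads,
# explicit backpropagation and Adam. Base R only; sized for small inputs
# (tens of pixels per side), which is all the test-scale presets need.
# Images are arrays of shape (H, W, C); weights are R arrays, so every
# forward/backward is a handful of matrix products per layer.

# ---- im2col / col2im ------------------------------------------------------

# Pad an (H, W, C) array symmetrically (mirror including the edge pixel).
pad_reflect <- function(x, top = 0, bottom = 0, left = 0, right = 0) {
  d <- dim(x)
  ri <- c(rev(seq_len(top)), seq_len(d[1]), d[1] - seq_len(bottom) + 1L)
  ci <- c(rev(seq_len(left)), seq_len(d[2]), d[2] - seq_len(right) + 1L)
  if (length(d) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}

pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

# Unfold k x k neighbourhoods of a zero-padded (H, W, C) array into an
# (H*W) x (k*k*C) matrix. Column blocks are ordered (dj outer, di inner),
# channels fastest, matching flatten_kernel().
im2col <- function(x, k, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  xp <- pad_zero(x, pad)
  blocks <- vector("list", k * k)
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sl <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE]
      blocks[[idx]] <- matrix(sl, H * W, C)
      idx <- idx + 1L
    }
  }
  do.call(cbind, blocks)
}

# Scatter-add the column gradient back to image space (adjoint of im2col).
col2im <- function(dcol, H, W, C, k, pad) {
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      block <- array(dcol[, ((idx - 1L) * C + 1L):(idx * C)], c(H, W, C))
      dxp[di:(di + H - 1L), dj:(dj + W - 1L), ] <-
        dxp[di:(di + H - 1L), dj:(dj + W - 1L), ] + block
      idx <- idx + 1L
    }
  }
  if (pad == 0L) dxp else dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
}

# Reshape a (k, k, Cin, Cout) kernel to the (k*k*Cin) x Cout matrix whose
# row order matches im2col's column order.
flatten_kernel <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3L, 1L, 2L, 4L)), d[1] * d[2] * d[3], d[4])
}

unflatten_kernel <- function(Wmat, k, Cin, Cout) {
  aperm(array(Wmat, c(Cin, k, k, Cout)), c(2L, 3L, 1L, 4L))
}

# ---- layers ---------------------------------------------------------------

conv_forward <- function(x, W, b) {
  k <- dim(W)[1]
  pad <- (k - 1L) %/% 2L
  d <- dim(x)
  col <- im2col(x, k, pad)
  y <- col %*% flatten_kernel(W)
  y <- sweep(y, 2L, b, "+")
  list(out = array(y, c(d[1], d[2], dim(W)[4])), col = col)
}

conv_backward <- function(dy, cache_col, x_dim, W) {
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  pad <- (k - 1L) %/% 2L
  dymat <- matrix(dy, prod(x_dim[1:2]), Cout)
  dWmat <- crossprod(cache_col, dymat)
  db <- colSums(dymat)
  dcol <- tcrossprod(dymat, flatten_kernel(W))
  dx <- col2im(dcol, x_dim[1], x_dim[2], Cin, k, pad)
  list(dx = dx, dW = unflatten_kernel(dWmat, k, Cin, Cout), db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  cand <- matrix(c(x[i1, j1, ], x[i2, j1, ], x[i1, j2, ], x[i2, j2, ]),
                 ncol = 4L)
  out <- array(pmax(cand[, 1L], cand[, 2L], cand[, 3L], cand[, 4L]),
               c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  which4 <- max.col(cand, ties.method = "first")
  list(out = out, which4 = which4, in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dx <- array(0, d)
  n <- h2 * w2 * d[3]
  # recover (i, j, c) of each pooled cell and route gradient to its argmax
  cell <- seq_len(n) - 1L
  ci <- cell %% h2
  cj <- (cell %/% h2) %% w2
  cc <- cell %/% (h2 * w2)
  off_i <- c(0L, 1L, 0L, 1L)[cache$which4]
  off_j <- c(0L, 0L, 1L, 1L)[cache$which4]
  lin <- (2L * ci + off_i + 1L) + d[1] * (2L * cj + off_j) + d[1] * d[2] * cc
  dx[lin] <- dy
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, d[1] * d[2], d[3])), in_dim = d)
}

gap_backward <- function(dy, in_dim) {
  n <- in_dim[1] * in_dim[2]
  array(rep(dy / n, each = n), in_dim)
}

dense_forward <- function(x, W, b) {
  list(out = drop(crossprod(W, x)) + b, x = x)
}

dense_backward <- function(dy, cache, W) {
  list(dx = drop(W %*% dy), dW = outer(cache$x, dy), db = dy)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Nearest-neighbour 2x upsampling (and its adjoint, 2x2 block sums).
upsample2_forward <- function(x) {
  d <- dim(x)
  idx_i <- rep(seq_len(d[1]), each = 2L)
  idx_j <- rep(seq_len(d[2]), each = 2L)
  x[idx_i, idx_j, , drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

# Instance normalization: per-sample, per-channel standardization with a
# learnable affine map. Keeps the dice-loss U-Net out of sigmoid
# saturation; deterministic at inference (no running statistics).
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, "-")
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(y, d), xhat = xhat, istd = istd)
}

instnorm_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  term <- sweep(dxhat, 2L, m1, "-") - sweep(cache$xhat, 2L, m2, "*")
  dx <- sweep(term, 2L, cache$istd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- initialisation and Adam ----------------------------------------------

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

he_dense <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         classes = c("numeric", "array", "matrix"), how = "replace")
}

# params, grads, state share one nested list structure.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

# elementwise sum of two parameter trees
tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

tree_scale <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_scale(a[[nm]], s)
    a
  } else {
    a * s
  }
}
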