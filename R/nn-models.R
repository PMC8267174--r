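# Concrete network architectures built on the engine in nn-core.R:
# the patch classifier (conv backbone -> global average pool -> 1,024-unit
# fully connected layer -> 2-way softmax) and a U-Net for tile
# segmentation. Both are plain nested lists of arrays, so checkpointing,
# Adam state and deterministic re-initialisation are trivial.

# ---- image resizing -------------------------------------------------------

#' @noRd
downscale_mean <- function(x, factor) {
  d <- dim(x)
  stopifnot(d[1] %% factor == 0L, d[2] %% factor == 0L)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  C <- if (length(d) == 3L) d[3] else 1L
  xm <- array(x, c(d[1], d[2], C))
  out <- array(0, c(h2, w2, C))
  for (c in seq_len(C)) {
    m <- matrix(xm[, , c], d[1], d[2])
    # average factor x factor blocks via two reshapes
    m <- matrix(colMeans(matrix(m, factor, h2 * d[2])), h2, d[2])
    m <- t(matrix(colMeans(matrix(t(m), factor, w2 * h2)), w2, h2))
    out[, , c] <- m
  }
  if (length(d) == 3L) out else out[, , 1L]
}

#' @noRd
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  C <- if (length(d) == 3L) d[3] else 1L
  xm <- array(x, c(d[1], d[2], C))
  # pixel-centre mapping; clamp to the valid range
  src_i <- (seq_len(out_h) - 0.5) * d[1] / out_h - 0.5
  src_j <- (seq_len(out_w) - 0.5) * d[2] / out_w - 0.5
  src_i <- pmin(pmax(src_i, 0), d[1] - 1)
  src_j <- pmin(pmax(src_j, 0), d[2] - 1)
  i0 <- pmin(floor(src_i), d[1] - 1); i1 <- pmin(i0 + 1, d[1] - 1)
  j0 <- pmin(floor(src_j), d[2] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  wi <- src_i - i0; wj <- src_j - j0
  out <- array(0, c(out_h, out_w, C))
  for (c in seq_len(C)) {
    m <- matrix(xm[, , c], d[1], d[2])
    a <- m[i0 + 1, j0 + 1, drop = FALSE] * outer(1 - wi, 1 - wj) +
      m[i1 + 1, j0 + 1, drop = FALSE] * outer(wi, 1 - wj) +
      m[i0 + 1, j1 + 1, drop = FALSE] * outer(1 - wi, wj) +
      m[i1 + 1, j1 + 1, drop = FALSE] * outer(wi, wj)
    out[, , c] <- a
  }
  if (length(d) == 3L) out else out[, , 1L]
}

# Resize a 0..255 RGB patch to the network input size and scale to [-1, 1].
#' @noRd
preprocess_patch <- function(img, size) {
  d <- dim(img)
  if (d[1] != size || d[2] != size) {
    if (d[1] %% size == 0L && d[1] == d[2]) {
      img <- downscale_mean(img, d[1] %/% size)
    } else {
      img <- resize_bilinear(img, size, size)
    }
  }
  img / 127.5 - 1
}

# ---- patch classifier ------------------------------------------------------

backbone_spec <- function(backbone) {
  switch(backbone,
    small_cnn = list(input_size = 32L, channels = c(8L, 16L, 32L, 64L),
                     pool_after = c(TRUE, TRUE, TRUE, FALSE)),
    inception_v3_class = list(input_size = 96L,
                              channels = c(32L, 64L, 128L, 256L, 256L),
                              pool_after = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    stop("unknown backbone: ", backbone, call. = FALSE)
  )
}

init_classifier_params <- function(spec, seed) {
  set.seed(seed)
  cin <- 3L
  convs <- vector("list", length(spec$channels))
  for (i in seq_along(spec$channels)) {
    cout <- spec$channels[i]
    convs[[i]] <- list(W = he_conv(3L, cin, cout), b = rep(0, cout))
    cin <- cout
  }
  Fw <- spec$channels[length(spec$channels)]
  list(conv = convs,
       fc = list(W = he_dense(Fw, 1024L), b = rep(0, 1024L)),
       out = list(W = he_dense(1024L, 2L), b = rep(0, 2L)))
}

# forward pass; with cache = TRUE returns everything backward needs
forward_classifier <- function(model, x, cache = FALSE) {
  p <- model$params
  spec <- model$spec
  caches <- if (cache) list(conv = vector("list", length(p$conv))) else NULL
  a <- x
  for (i in seq_along(p$conv)) {
    cf <- conv_forward(a, p$conv[[i]]$W, p$conv[[i]]$b)
    st <- list(col = cf$col, in_dim = dim(a))
    z <- cf$out
    if (!is.null(p$conv[[i]]$g)) {         # instance norm where configured
      nf <- instnorm_forward(z, p$conv[[i]]$g, p$conv[[i]]$be)
      z <- nf$out
      st$xhat <- nf$xhat; st$istd <- nf$istd
    }
    rf <- relu_forward(z)
    st$mask <- rf$mask
    a <- rf$out
    if (cache) st$act <- a                 # post-relu activation (Grad-CAM)
    if (spec$pool_after[i]) {
      pf <- maxpool_forward(a)
      st$pool <- pf[c("which4", "in_dim")]
      a <- pf$out
    }
    if (cache) caches$conv[[i]] <- st
  }
  gp <- gap_forward(a)
  fc <- dense_forward(gp$out, p$fc$W, p$fc$b)
  fr <- relu_forward(fc$out)
  out <- dense_forward(fr$out, p$out$W, p$out$b)
  probs <- softmax(out$out)
  if (cache) {
    caches$last_act <- a
    caches$gap_dim <- gp$in_dim
    caches$feat <- gp$out
    caches$fc_x <- fc$x
    caches$fc_mask <- fr$mask
    caches$hidden <- fr$out
  }
  list(probs = probs, logits = out$out, caches = caches)
}

# dlogits -> gradients for every parameter; also captures the gradient at
# the post-relu activation of `capture_layer` (used by Grad-CAM)
backward_classifier <- function(model, caches, dlogits,
                                capture_layer = length(model$params$conv)) {
  p <- model$params
  spec <- model$spec
  g_out <- dense_backward(dlogits, list(x = caches$hidden), p$out$W)
  dh <- g_out$dx * caches$fc_mask
  g_fc <- dense_backward(dh, list(x = caches$fc_x), p$fc$W)
  dA <- gap_backward(g_fc$dx, caches$gap_dim)
  d_act <- NULL
  grads_conv <- vector("list", length(p$conv))
  da <- dA
  for (i in rev(seq_along(p$conv))) {
    st <- caches$conv[[i]]
    if (spec$pool_after[i]) da <- maxpool_backward(da, st$pool)
    if (i == capture_layer) d_act <- da
    da <- da * st$mask
    gi <- NULL
    if (!is.null(p$conv[[i]]$g)) {
      nb <- instnorm_backward(da, st, p$conv[[i]]$g)
      da <- nb$dx
      gi <- list(g = nb$dgamma, be = nb$dbeta)
    }
    gb <- conv_backward(da, st$col, st$in_dim, p$conv[[i]]$W)
    grads_conv[[i]] <- c(list(W = gb$dW, b = gb$db), gi)
    da <- gb$dx
  }
  list(grads = list(conv = grads_conv,
                    fc = list(W = g_fc$dW, b = g_fc$db),
                    out = list(W = g_out$dW, b = g_out$db)),
       d_act = d_act)
}

count_params <- function(params) {
  s <- 0L
  rapply(params, function(p) s <<- s + length(p), how = "unlist",
         classes = c("numeric", "matrix", "array"))
  s
}

# ---- U-Net -----------------------------------------------------------------

init_unet_params <- function(depth, base_filters, seed, in_channels = 3L) {
  set.seed(seed)
  # conv -> [instance norm (learnable affine)] -> relu. The first encoder
  # level and the final decoder fusion stay un-normalized: per-sample
  # normalization erases absolute intensity, and this input -> skip ->
  # output path is what carries the tissue's overall darkness; the
  # normalized deeper blocks keep dice-loss training out of saturation.
  block <- function(k, cin, cout, norm = TRUE) {
    p <- list(W = he_conv(k, cin, cout), b = rep(0, cout))
    if (norm) {
      p$g <- rep(1, cout)
      p$be <- rep(0, cout)
    }
    p
  }
  enc <- vector("list", depth)
  cin <- in_channels
  for (i in seq_len(depth)) {
    ch <- base_filters * 2L^(i - 1L)
    enc[[i]] <- list(c1 = block(3L, cin, ch, norm = i > 1L),
                     c2 = block(3L, ch, ch, norm = i > 1L))
    cin <- ch
  }
  chb <- base_filters * 2L^depth
  bott <- list(c1 = block(3L, cin, chb), c2 = block(3L, chb, chb))
  dec <- vector("list", depth)
  cin <- chb
  for (i in rev(seq_len(depth))) {
    ch <- base_filters * 2L^(i - 1L)
    dec[[i]] <- list(up = block(3L, cin, ch),
                     c1 = block(3L, 2L * ch, ch, norm = i > 1L))
    cin <- ch
  }
  out <- list(W = he_conv(1L, base_filters, 1L), b = 0)
  list(enc = enc, bott = bott, dec = dec, out = out)
}

conv_relu <- function(a, prm, cache) {
  cf <- conv_forward(a, prm$W, prm$b)
  z <- cf$out
  nf <- NULL
  if (!is.null(prm$g)) {                     # instance norm where configured
    nf <- instnorm_forward(z, prm$g, prm$be)
    z <- nf$out
  }
  rf <- relu_forward(z)
  list(out = rf$out,
       st = if (cache) list(col = cf$col, in_dim = dim(a), mask = rf$mask,
                            xhat = nf$xhat, istd = nf$istd))
}

# backward through one conv -> [instance norm] -> relu block
conv_relu_backward <- function(da, st, prm) {
  da <- da * st$mask
  gi <- NULL
  if (!is.null(prm$g)) {
    nb <- instnorm_backward(da, st, prm$g)
    da <- nb$dx
    gi <- list(g = nb$dgamma, be = nb$dbeta)
  }
  cb <- conv_backward(da, st$col, st$in_dim, prm$W)
  list(dx = cb$dx, g = c(list(W = cb$dW, b = cb$db), gi))
}

forward_unet <- function(params, x, cache = FALSE) {
  depth <- length(params$enc)
  skips <- vector("list", depth)
  caches <- list(enc = vector("list", depth), dec = vector("list", depth))
  a <- x
  for (i in seq_len(depth)) {
    r1 <- conv_relu(a, params$enc[[i]]$c1, cache)
    r2 <- conv_relu(r1$out, params$enc[[i]]$c2, cache)
    skips[[i]] <- r2$out
    pf <- maxpool_forward(r2$out)
    caches$enc[[i]] <- list(c1 = r1$st, c2 = r2$st,
                            pool = if (cache) pf[c("which4", "in_dim")])
    a <- pf$out
  }
  b1 <- conv_relu(a, params$bott$c1, cache)
  b2 <- conv_relu(b1$out, params$bott$c2, cache)
  caches$bott <- list(c1 = b1$st, c2 = b2$st)
  a <- b2$out
  for (i in rev(seq_len(depth))) {
    up <- upsample2_forward(a)
    r1 <- conv_relu(up, params$dec[[i]]$up, cache)
    cat_in <- array(c(r1$out, skips[[i]]),
                    c(dim(r1$out)[1], dim(r1$out)[2],
                      dim(r1$out)[3] + dim(skips[[i]])[3]))
    r2 <- conv_relu(cat_in, params$dec[[i]]$c1, cache)
    caches$dec[[i]] <- list(up = r1$st, c1 = r2$st,
                            split = dim(r1$out)[3])
    a <- r2$out
  }
  of <- conv_forward(a, params$out$W, params$out$b)
  z <- of$out[, , 1L]
  # clamp the logit so the sigmoid never saturates fully: keeps the dice
  # gradient alive and an all-positive collapse recoverable
  zc <- pmin(pmax(z, -4), 4)
  prob <- sigmoid(zc)
  caches$out <- if (cache) list(col = of$col, in_dim = dim(a))
  list(prob = prob, grad_mask = (abs(z) < 4) * 1,
       caches = if (cache) caches)
}

backward_unet <- function(params, caches, dz_out) {
  depth <- length(params$enc)
  g <- list(enc = vector("list", depth), dec = vector("list", depth))
  ob <- conv_backward(array(dz_out, c(dim(dz_out), 1L)), caches$out$col,
                      caches$out$in_dim, params$out$W)
  g$out <- list(W = ob$dW, b = ob$db)
  da <- ob$dx
  dskip <- vector("list", depth)
  # decoder blocks in reverse execution order: outermost (i = 1) ran last
  for (i in seq_len(depth)) {
    st <- caches$dec[[i]]
    cb <- conv_relu_backward(da, st$c1, params$dec[[i]]$c1)
    k <- st$split
    d_up_out <- cb$dx[, , seq_len(k), drop = FALSE]
    dskip[[i]] <- cb$dx[, , (k + 1L):dim(cb$dx)[3], drop = FALSE]
    ub <- conv_relu_backward(d_up_out, st$up, params$dec[[i]]$up)
    g$dec[[i]] <- list(up = ub$g, c1 = cb$g)
    da <- upsample2_backward(ub$dx)
  }
  # bottleneck
  b2 <- conv_relu_backward(da, caches$bott$c2, params$bott$c2)
  b1 <- conv_relu_backward(b2$dx, caches$bott$c1, params$bott$c1)
  g$bott <- list(c1 = b1$g, c2 = b2$g)
  da <- b1$dx
  # encoder blocks deepest-first; skip gradients join before the pool input
  for (i in rev(seq_len(depth))) {
    st <- caches$enc[[i]]
    da <- maxpool_backward(da, st$pool) + dskip[[i]]
    c2 <- conv_relu_backward(da, st$c2, params$enc[[i]]$c2)
    c1 <- conv_relu_backward(c2$dx, st$c1, params$enc[[i]]$c1)
    g$enc[[i]] <- list(c1 = c1$g, c2 = c2$g)
    da <- c1$dx
  }
  g
}

# soft dice of a probability map against a binary mask, plus its gradient
# with respect to the pre-sigmoid logits (the 1 - dice training loss)
dice_forward_backward <- function(prob, truth, eps) {
  sp <- sum(prob); st <- sum(truth); spt <- sum(prob * truth)
  denom <- sp + st + eps
  dice <- (2 * spt + eps) / denom
  dprob <- -(2 * truth * denom - (2 * spt + eps)) / denom^2
  dz <- dprob * prob * (1 - prob)
  list(dice = dice, loss = 1 - dice, dz = dz)
}
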