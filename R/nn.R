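# Minimal convolutional-network engine used by the acceptability classifier.
#
# Tensors are numeric arrays dim (H, W, C, N). Convolutions are 3x3, pad 1,
# stride 1, computed as im2col gathers followed by a single BLAS matrix
# multiply per sample; weights for a layer are stored as a (9*C_in, C_out)
# matrix whose rows are ordered (dy, dx, channel), dy fastest. Pooling is
# 2x2/stride 2. Everything is plain R so gradients (needed for both training
# and Grad-CAM) are explicit.

# Linear indices of all 3x3 patches into a zero-padded (H+2, W+2, C) block.
conv_patch_idx <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)        # output row, column-major order
  j <- rep(seq_len(W), each = H)         # output col
  off <- expand.grid(dy = 0:2, dx = 0:2, c = seq_len(C) - 1L)
  idx <- matrix(0L, H * W, nrow(off))
  for (k in seq_len(nrow(off))) {
    idx[, k] <- off$c[k] * Hp * Wp + (j + off$dx[k] - 1L) * Hp +
      (i + off$dy[k])
  }
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

conv_forward <- function(x, Wmat, b, idx) {
  d <- dim(x); N <- d[4]; F <- ncol(Wmat)
  xp <- pad1(x)
  npix <- nrow(idx)
  # batched im2col: rows ordered (pixel within sample, sample)
  Xcol <- matrix(0, npix * N, ncol(idx))
  for (n in seq_len(N)) {
    xpn <- xp[, , , n]
    Xcol[(n - 1L) * npix + seq_len(npix), ] <- xpn[idx]
  }
  y <- Xcol %*% Wmat
  y <- y + rep(b, each = nrow(y))
  y <- aperm(array(y, dim = c(d[1], d[2], N, F)), c(1, 2, 4, 3))
  list(y = y, Xcol = Xcol)
}

conv_backward <- function(dy, Xcol, Wmat, idx, in_dim) {
  # dy: (H, W, F, N); returns dW, db, dx
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]; N <- in_dim[4]
  npix <- H * W
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), npix * N, dim(dy)[3])
  dW <- crossprod(Xcol, dym)
  db <- colSums(dym)
  dXcol <- tcrossprod(dym, Wmat)
  flat <- (H + 2L) * (W + 2L) * C
  dxp <- array(0, dim = c(H + 2L, W + 2L, C, N))
  base <- rep((seq_len(N) - 1L) * flat, each = npix)
  # within one patch-offset column the target pixels are distinct per sample
  for (k in seq_len(ncol(idx))) {
    tgt <- rep(idx[, k], times = N) + base
    dxp[tgt] <- dxp[tgt] + dXcol[, k]
  }
  list(dW = dW, db = db,
       dx = dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE])
}

# leaky rectifier (slope 0.1): keeps units trainable under heavy
# augmentation, where hard ReLUs are prone to dying at small batch sizes
relu_forward <- function(x) pmax(x, 0.1 * x)
relu_backward <- function(dy, y) dy * ((y > 0) + 0.1 * (y <= 0))

pool_quads <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  list(a11 = x[ro, co, , , drop = FALSE],
       a21 = x[ro + 1L, co, , , drop = FALSE],
       a12 = x[ro, co + 1L, , , drop = FALSE],
       a22 = x[ro + 1L, co + 1L, , , drop = FALSE])
}

maxpool_forward <- function(x) {
  q <- pool_quads(x)
  y <- pmax(q$a11, q$a21, q$a12, q$a22)
  m11 <- q$a11 == y
  m21 <- (q$a21 == y) & !m11
  m12 <- (q$a12 == y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(y = y, masks = list(m11, m21, m12, m22))
}

maxpool_backward <- function(dy, masks, in_dim) {
  dx <- array(0, dim = in_dim)
  ro <- seq(1L, in_dim[1], by = 2L); co <- seq(1L, in_dim[2], by = 2L)
  dx[ro, co, , ] <- dy * masks[[1]]
  dx[ro + 1L, co, , ] <- dy * masks[[2]]
  dx[ro, co + 1L, , ] <- dy * masks[[3]]
  dx[ro + 1L, co + 1L, , ] <- dy * masks[[4]]
  dx
}

avgpool2 <- function(x) {
  q <- pool_quads(x)
  (q$a11 + q$a21 + q$a12 + q$a22) / 4
}

# He-normal initialization of the network parameters.
nn_init_params <- function(seed, channels = c(8L, 16L, 32L)) {
  set.seed(seed)
  he <- function(fan_in, nr, nc)
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  list(W1 = he(9 * 1, 9 * 1, c1), b1 = numeric(c1),
       W2 = he(9 * c1, 9 * c1, c2), b2 = numeric(c2),
       W3 = he(9 * c2, 9 * c2, c3), b3 = numeric(c3),
       Wf = he(c3, c3, 2L), bf = numeric(2L))
}

nn_geometry <- function(channels = c(8L, 16L, 32L)) {
  list(idx1 = conv_patch_idx(56L, 56L, 1L),
       idx2 = conv_patch_idx(28L, 28L, channels[1]),
       idx3 = conv_patch_idx(14L, 14L, channels[2]),
       channels = channels)
}

# Forward pass. x: (224, 224, N) grayscale on [0, 255]. Returns logits
# (2 x N), probs, and (optionally) the cache needed for backward/Grad-CAM.
nn_forward <- function(params, geom, x, keep = FALSE) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  N <- dim(x)[3]
  x <- array(x / 255, dim = c(224L, 224L, 1L, N))  # background maps to 0
  s <- avgpool2(avgpool2(x))                         # stride-4 stem -> 56
  cv1 <- conv_forward(s, params$W1, params$b1, geom$idx1)
  a1 <- relu_forward(cv1$y)
  p1 <- maxpool_forward(a1)                          # 28
  cv2 <- conv_forward(p1$y, params$W2, params$b2, geom$idx2)
  a2 <- relu_forward(cv2$y)
  p2 <- maxpool_forward(a2)                          # 14
  cv3 <- conv_forward(p2$y, params$W3, params$b3, geom$idx3)
  a3 <- relu_forward(cv3$y)                          # Grad-CAM target, 14x14
  p3 <- maxpool_forward(a3)                          # 7
  F3 <- dim(a3)[3]
  g <- matrix(colMeans(matrix(p3$y, 7L * 7L, F3 * N)), F3, N)
  logits <- crossprod(params$Wf, g) + params$bf      # 2 x N
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), "/")
  out <- list(logits = logits, probs = probs)
  if (keep)
    out$cache <- list(s = s, cv1 = cv1, a1 = a1, p1 = p1, cv2 = cv2, a2 = a2,
                      p2 = p2, cv3 = cv3, a3 = a3, p3 = p3, g = g, N = N)
  out
}

# Backward pass of mean cross-entropy. y: integer vector in {1, 2} (class
# index, 2 = unacceptable). Returns gradients named like the parameters.
nn_backward <- function(params, geom, fwd, y) {
  cache <- fwd$cache; N <- cache$N
  F3 <- geom$channels[3]
  dlogits <- fwd$probs
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  dlogits <- dlogits / N
  dWf <- tcrossprod(cache$g, dlogits)
  dbf <- rowSums(dlogits)
  dg <- params$Wf %*% dlogits                         # F3 x N
  dp3 <- array(rep(dg, each = 7L * 7L) / (7 * 7),
               dim = c(7L, 7L, F3, N))
  da3 <- maxpool_backward(dp3, cache$p3$masks, dim(cache$a3))
  dcv3 <- relu_backward(da3, cache$a3)
  bk3 <- conv_backward(dcv3, cache$cv3$Xcol, params$W3, geom$idx3,
                       dim(cache$p2$y))
  da2 <- maxpool_backward(bk3$dx, cache$p2$masks, dim(cache$a2))
  dcv2 <- relu_backward(da2, cache$a2)
  bk2 <- conv_backward(dcv2, cache$cv2$Xcol, params$W2, geom$idx2,
                       dim(cache$p1$y))
  da1 <- maxpool_backward(bk2$dx, cache$p1$masks, dim(cache$a1))
  dcv1 <- relu_backward(da1, cache$a1)
  bk1 <- conv_backward(dcv1, cache$cv1$Xcol, params$W1, geom$idx1,
                       dim(cache$s))
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = bk3$dW, b3 = bk3$db, Wf = dWf, bf = dbf)
}

nn_loss <- function(probs, y) {
  p <- probs[cbind(y, seq_len(ncol(probs)))]
  -mean(log(pmax(p, 1e-12)))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
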