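# Minimal neural-network primitives used by the paired encoders.
#
# Layout conventions: the batch is always the LAST array dimension.
#   1-D signals: [channels, time, batch]
#   2-D grids:   [channels, height, width, batch]
#   vectors:     [features, batch]
# Convolutions use kernel 3, stride 1, padding 1 throughout, so temporal
# and spatial extents are preserved exactly (the shape-preserving padding
# convention).  A k=3 convolution over T positions is computed as a single
# matrix product W [C_out x 3*C_in] times the stack of the left-shifted,
# centred and right-shifted zero-padded input, which keeps everything in
# BLAS.  Each *_fwd returns list(out, cache); each *_bwd takes (d_out,
# cache) and returns list(dx, and per-parameter gradients where relevant).

# The three taps are applied as three GEMMs on the unshifted input with
# the tap-1/tap-3 products added into shifted output columns; `jgt1` /
# `jltT` index the columns whose time position is > 1 / < Tn within each
# batch item, so shifts never cross an item boundary (zero padding).
conv1d_fwd <- function(x, w, b) {
  d <- dim(x); C <- d[1L]; Tn <- d[2L]; B <- d[3L]
  xm <- matrix(x, C, Tn * B)
  w1 <- w[, 1L:C, drop = FALSE]             # taps on x_{t-1}
  w2 <- w[, C + 1L:C, drop = FALSE]         # taps on x_t
  w3 <- w[, 2L * C + 1L:C, drop = FALSE]    # taps on x_{t+1}
  y <- w2 %*% xm
  y1 <- w1 %*% xm
  y3 <- w3 %*% xm
  t_of <- rep.int(seq_len(Tn), B)
  jgt1 <- which(t_of > 1L)
  jltT <- which(t_of < Tn)
  y[, jgt1] <- y[, jgt1, drop = FALSE] + y1[, jgt1 - 1L, drop = FALSE]
  y[, jltT] <- y[, jltT, drop = FALSE] + y3[, jltT + 1L, drop = FALSE]
  y <- y + b
  list(out = array(y, c(nrow(w), Tn, B)),
       cache = list(xm = xm, w1 = w1, w2 = w2, w3 = w3, dims = d,
                    jgt1 = jgt1, jltT = jltT))
}

conv1d_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1L]; Tn <- d[2L]; B <- d[3L]
  xm <- cache$xm; jgt1 <- cache$jgt1; jltT <- cache$jltT
  dym <- matrix(dy, length(dy) / (Tn * B), Tn * B)
  db <- rowSums(dym)
  dw2 <- tcrossprod(dym, xm)
  dw1 <- tcrossprod(dym[, jgt1, drop = FALSE],
                    xm[, jgt1 - 1L, drop = FALSE])
  dw3 <- tcrossprod(dym[, jltT, drop = FALSE],
                    xm[, jltT + 1L, drop = FALSE])
  dxm <- crossprod(cache$w2, dym)
  g1 <- crossprod(cache$w1, dym)
  dxm[, jltT] <- dxm[, jltT, drop = FALSE] + g1[, jltT + 1L, drop = FALSE]
  g3 <- crossprod(cache$w3, dym)
  dxm[, jgt1] <- dxm[, jgt1, drop = FALSE] + g3[, jgt1 - 1L, drop = FALSE]
  list(dx = array(dxm, d), dw = cbind(dw1, dw2, dw3), db = db)
}

conv2d_fwd <- function(x, w, b) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
  xp <- array(0, c(C, H + 2L, W + 2L, B))
  xp[, 2L:(H + 1L), 2L:(W + 1L), ] <- x
  blocks <- vector("list", 9L)
  for (di in 0:2) for (dj in 0:2)
    blocks[[di * 3L + dj + 1L]] <-
      matrix(xp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE],
             C, H * W * B)
  xs <- do.call(rbind, blocks)
  y <- w %*% xs + b
  list(out = array(y, c(nrow(w), H, W, B)),
       cache = list(xs = xs, w = w, dims = d))
}

conv2d_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
  dym <- matrix(dy, dim(cache$w)[1L], H * W * B)
  dw <- tcrossprod(dym, cache$xs)
  db <- rowSums(dym)
  dxs <- crossprod(cache$w, dym)
  dxp <- array(0, c(C, H + 2L, W + 2L, B))
  for (di in 0:2) for (dj in 0:2) {
    k <- di * 3L + dj
    blk <- array(dxs[(k * C + 1L):((k + 1L) * C), , drop = FALSE],
                 c(C, H, W, B))
    dxp[, di + seq_len(H), dj + seq_len(W), ] <-
      dxp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE] + blk
  }
  list(dx = dxp[, 2L:(H + 1L), 2L:(W + 1L), , drop = FALSE],
       dw = dw, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_bwd <- function(dy, cache) dy * cache

# Max-pool of width 2 along the second dimension of a 3-D array; an odd
# trailing element is dropped (and receives zero gradient).
pool_dim2_fwd <- function(x) {
  d <- dim(x); T2 <- d[2L] %/% 2L
  i1 <- seq.int(1L, by = 2L, length.out = T2); i2 <- i1 + 1L
  a <- x[, i1, , drop = FALSE]; b <- x[, i2, , drop = FALSE]
  mask <- a >= b
  list(out = a * mask + b * !mask,
       cache = list(mask = mask, dims = d, i1 = i1, i2 = i2))
}

pool_dim2_bwd <- function(dy, cache) {
  dx <- array(0, cache$dims)
  dx[, cache$i1, ] <- dy * cache$mask
  dx[, cache$i2, ] <- dy * !cache$mask
  dx
}

pool1d_fwd <- pool_dim2_fwd
pool1d_bwd <- pool_dim2_bwd

# 2x2 max-pool on [C, H, W, B]; a dimension of extent 1 (e.g. the height
# of an audio grid) is left untouched.
pool2d_fwd <- function(x) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
  cache <- list(dims = d)
  if (H > 1L) {
    p <- pool_dim2_fwd(array(x, c(C, H, W * B)))
    H <- dim(p$out)[2L]
    x <- array(p$out, c(C, H, W, B))
    cache$h <- p$cache
  }
  if (W > 1L) {
    p <- pool_dim2_fwd(array(x, c(C * H, W, B)))
    W <- dim(p$out)[2L]
    x <- array(p$out, c(C, H, W, B))
    cache$w <- p$cache
  }
  cache$out_dims <- c(C, H, W, B)
  list(out = x, cache = cache)
}

pool2d_bwd <- function(dy, cache) {
  d <- cache$out_dims; C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
  if (!is.null(cache$w)) {
    dy <- pool_dim2_bwd(array(dy, c(C * H, W, B)), cache$w)
    W <- cache$w$dims[2L]
    dy <- array(dy, c(C, H, W, B))
  }
  if (!is.null(cache$h)) {
    dy <- pool_dim2_bwd(array(dy, c(C, H, W * B)), cache$h)
    dy <- array(dy, cache$dims)
  }
  dy
}

# Global average pooling over all spatial dims -> [C, B].
gap_fwd <- function(x) {
  d <- dim(x); C <- d[1L]; B <- d[length(d)]
  S <- prod(d[-c(1L, length(d))])
  x3 <- array(x, c(C, S, B))
  out <- colMeans(aperm(x3, c(2L, 1L, 3L)), dims = 1L)
  list(out = matrix(out, C, B), cache = list(dims = d, S = S))
}

gap_bwd <- function(dy, cache) {
  C <- cache$dims[1L]; B <- cache$dims[length(cache$dims)]
  S <- cache$S
  dx3 <- aperm(array(dy / S, c(C, B, S)), c(1L, 3L, 2L))
  array(dx3, cache$dims)
}

linear_fwd <- function(x, w, b) {
  list(out = w %*% x + b, cache = list(x = x, w = w))
}

linear_bwd <- function(dy, cache) {
  list(dx = crossprod(cache$w, dy), dw = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

# He-style initialization for a weight matrix [fan_out x fan_in].
init_weight <- function(fan_out, fan_in) {
  matrix(stats::rnorm(fan_out * fan_in, sd = sqrt(2 / fan_in)),
         fan_out, fan_in)
}

# ---- Adam over arbitrary nested parameter lists ------------------------

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) tree_map(f, a[[i]]))
           else lapply(seq_along(a), function(i) tree_map(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                  state$m, state$v)
  list(params = tree_map(`-`, params, upd), state = state)
}

tree_max_abs <- function(x) {
  if (is.list(x)) {
    if (!length(x)) return(0)
    max(vapply(x, tree_max_abs, numeric(1)))
  } else max(abs(x), 0)
}

tree_n_params <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_n_params, numeric(1))) else length(x)
}
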