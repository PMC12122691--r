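# Finite-difference audits of every analytic backward pass.

test_that("conv1d preserves length and matches numerical gradients", {
  set.seed(11)
  x <- array(rnorm(3 * 9 * 2), c(3, 9, 2))
  w <- predann:::init_weight(5, 9); b <- rnorm(5)
  f <- predann:::conv1d_fwd(x, w, b)
  expect_identical(dim(f$out), c(5L, 9L, 2L))   # extent preserved (k3 p1)
  dy <- array(rnorm(length(f$out)), dim(f$out))
  bk <- predann:::conv1d_bwd(dy, f$cache)
  gx <- numerical_grad(function(v)
    sum(predann:::conv1d_fwd(v, w, b)$out * dy), x)
  gw <- numerical_grad(function(v)
    sum(predann:::conv1d_fwd(x, v, b)$out * dy), w)
  gb <- numerical_grad(function(v)
    sum(predann:::conv1d_fwd(x, w, v)$out * dy), b)
  expect_lt(max(abs(gx - bk$dx)), 1e-6)
  expect_lt(max(abs(gw - bk$dw)), 1e-6)
  expect_lt(max(abs(gb - bk$db)), 1e-6)
})

test_that("conv2d preserves extents and matches numerical gradients", {
  set.seed(12)
  x <- array(rnorm(2 * 4 * 5 * 2), c(2, 4, 5, 2))
  w <- predann:::init_weight(3, 18); b <- rnorm(3)
  f <- predann:::conv2d_fwd(x, w, b)
  expect_identical(dim(f$out), c(3L, 4L, 5L, 2L))
  dy <- array(rnorm(length(f$out)), dim(f$out))
  bk <- predann:::conv2d_bwd(dy, f$cache)
  gx <- numerical_grad(function(v)
    sum(predann:::conv2d_fwd(v, w, b)$out * dy), x)
  gw <- numerical_grad(function(v)
    sum(predann:::conv2d_fwd(x, v, b)$out * dy), w)
  expect_lt(max(abs(gx - bk$dx)), 1e-6)
  expect_lt(max(abs(gw - bk$dw)), 1e-6)
  # height-1 grids (audio layout) pass through unchanged in height
  xa <- array(rnorm(1 * 1 * 8 * 2), c(1, 1, 8, 2))
  wa <- predann:::init_weight(2, 9)
  fa <- predann:::conv2d_fwd(xa, wa, rnorm(2))
  expect_identical(dim(fa$out), c(2L, 1L, 8L, 2L))
})

test_that("max-pooling halves extents and routes gradients to maxima", {
  set.seed(13)
  x <- array(rnorm(2 * 8 * 2), c(2, 8, 2))
  f <- predann:::pool1d_fwd(x)
  expect_identical(dim(f$out), c(2L, 4L, 2L))
  dy <- array(rnorm(length(f$out)), dim(f$out))
  bk <- predann:::pool1d_bwd(dy, f$cache)
  gx <- numerical_grad(function(v)
    sum(predann:::pool1d_fwd(v)$out * dy), x)
  expect_lt(max(abs(gx - bk)), 1e-6)
  # 2-D pooling, including a height-1 grid
  x2 <- array(rnorm(2 * 4 * 6 * 2), c(2, 4, 6, 2))
  f2 <- predann:::pool2d_fwd(x2)
  expect_identical(dim(f2$out), c(2L, 2L, 3L, 2L))
  dy2 <- array(rnorm(length(f2$out)), dim(f2$out))
  gx2 <- numerical_grad(function(v)
    sum(predann:::pool2d_fwd(v)$out * dy2), x2)
  expect_lt(max(abs(gx2 - predann:::pool2d_bwd(dy2, f2$cache))), 1e-6)
  x3 <- array(rnorm(1 * 1 * 6 * 2), c(1, 1, 6, 2))
  f3 <- predann:::pool2d_fwd(x3)
  expect_identical(dim(f3$out), c(1L, 1L, 3L, 2L))
})

test_that("global average pooling and linear layers backpropagate", {
  set.seed(14)
  x <- array(rnorm(3 * 7 * 2), c(3, 7, 2))
  f <- predann:::gap_fwd(x)
  expect_identical(dim(f$out), c(3L, 2L))
  expect_equal(f$out[2, 1], mean(x[2, , 1]))
  dy <- matrix(rnorm(6), 3, 2)
  gx <- numerical_grad(function(v)
    sum(predann:::gap_fwd(v)$out * dy), x)
  expect_lt(max(abs(gx - predann:::gap_bwd(dy, f$cache))), 1e-6)

  xl <- matrix(rnorm(8), 4, 2); wl <- matrix(rnorm(12), 3, 4); bl <- rnorm(3)
  fl <- predann:::linear_fwd(xl, wl, bl)
  dyl <- matrix(rnorm(6), 3, 2)
  bkl <- predann:::linear_bwd(dyl, fl$cache)
  gwl <- numerical_grad(function(v)
    sum(predann:::linear_fwd(xl, v, bl)$out * dyl), wl)
  expect_lt(max(abs(gwl - bkl$dw)), 1e-6)
})

test_that("a whole branch backward pass matches numerical gradients", {
  set.seed(15)
  spec <- encoder_spec(channels_per_block = c(3, 4), embedding_dim = 5)
  branch <- predann:::with_seed(9, predann:::init_branch(spec, 2, 3))
  x <- array(rnorm(2 * 12 * 2), c(2, 12, 2))
  dz1 <- matrix(rnorm(3 * 2), 3, 2)
  dz2 <- matrix(rnorm(5 * 2), 5, 2)
  fw <- predann:::branch_fwd(branch, spec, x)
  g <- predann:::branch_bwd(branch, spec, fw, dz1, dz2)
  obj <- function(br) {
    f <- predann:::branch_fwd(br, spec, x)
    sum(f$z1 * dz1) + sum(f$z2 * dz2)
  }
  # audit one weight array per component
  for (path in list(c("blocks", "1", "w"), c("blocks", "2", "w"),
                    c("proj1", "w"), c("proj2", "w1"), c("proj2", "w2"))) {
    leaf <- if (path[1] == "blocks") branch$blocks[[as.integer(path[2])]]$w
            else branch[[path[1]]][[path[2]]]
    gleaf <- if (path[1] == "blocks") g$blocks[[as.integer(path[2])]]$w
             else g[[path[1]]][[path[2]]]
    num <- numerical_grad(function(v) {
      br <- branch
      if (path[1] == "blocks") br$blocks[[as.integer(path[2])]]$w <- v
      else br[[path[1]]][[path[2]]] <- v
      obj(br)
    }, leaf, eps = 1e-5)
    expect_lt(max(abs(num - gleaf)), 1e-5)
  }
})

test_that("Adam updates every leaf and reduces a quadratic", {
  params <- list(a = matrix(5, 2, 2), b = list(c = rep(-3, 4)))
  st <- predann:::adam_init(params)
  for (i in 1:300) {
    grads <- predann:::tree_map(function(p) 2 * p, params)  # d/dp sum(p^2)
    up <- predann:::adam_step(params, grads, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(predann:::tree_max_abs(params), 0.5)
  expect_equal(predann:::tree_n_params(params), 8)
})
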