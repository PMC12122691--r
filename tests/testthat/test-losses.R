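test_that("cross-entropy matches closed forms and is additive", {
  expect_equal(classification_loss(matrix(0, 1, 10), 0), log(10))
  # concentrated logits drive the loss to zero
  hot <- matrix(c(50, rep(0, 9)), 1, 10)
  expect_lt(classification_loss(hot, 0), 1e-10)
  # B = 2 equals the sum of the two B = 1 losses
  set.seed(21)
  l1 <- matrix(rnorm(10), 1); l2 <- matrix(rnorm(10), 1)
  expect_equal(classification_loss(rbind(l1, l2), c(3, 8)),
               classification_loss(l1, 3) + classification_loss(l2, 8))
  expect_error(classification_loss(l1, 10), "labels")
  expect_error(classification_loss(l1, -1), "labels")
})

test_that("classification gradient matches finite differences", {
  set.seed(22)
  logits <- matrix(rnorm(12), 4, 3)
  labels <- c(0, 2, 1, 0)
  g <- predann:::classification_loss_grad(logits, labels)
  num <- numerical_grad(function(v) classification_loss(v, labels), logits)
  expect_lt(max(abs(num - g$grad)), 1e-7)
})

test_that("cosine similarity has the defining properties", {
  v <- c(1, 2, -3)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(v, 7 * v), 1)   # scale invariance
  expect_error(cosine_similarity(c(0, 0), v[1:2]), "zero vector")
})

test_that("PredANN loss reproduces its closed-form special cases", {
  # single pair: each softmax has one candidate
  expect_equal(predann_loss(matrix(1:3, 1), matrix(4:6, 1)), 0)
  # matched orthonormal pairs at B = 2, tau = 1
  expect_equal(predann_loss(diag(2), diag(2), loss_config(temperature = 1)),
               4 * log(1 + exp(-1)), tolerance = 1e-12)
  # all embeddings identical: every softmax uniform -> 2B log B
  for (B in c(2, 3, 5)) {
    Z <- matrix(rep(c(1, 2), each = B), B, 2)
    expect_equal(predann_loss(Z, Z, loss_config(temperature = 0.3)),
                 2 * B * log(B), tolerance = 1e-10)
  }
})

test_that("PredANN loss agrees with the brute-force double loop", {
  set.seed(23)
  for (B in c(2, 3, 5, 8)) {
    M <- matrix(rnorm(B * 6), B)
    E <- matrix(rnorm(B * 6), B)
    tau <- runif(1, 0.05, 1)
    expect_equal(predann_loss(M, E, loss_config(temperature = tau)),
                 brute_force_predann(M, E, tau), tolerance = 1e-10)
  }
})

test_that("PredANN loss is invariant to row rescaling and permutation", {
  set.seed(24)
  B <- 5
  M <- matrix(rnorm(B * 4), B); E <- matrix(rnorm(B * 4), B)
  cfg <- loss_config(temperature = 0.2)
  base <- predann_loss(M, E, cfg)
  expect_equal(predann_loss(M * runif(B, 0.1, 9), E, cfg), base,
               tolerance = 1e-10)
  expect_equal(predann_loss(M, E * runif(B, 0.1, 9), cfg), base,
               tolerance = 1e-10)
  p <- sample(B)
  expect_equal(predann_loss(M[p, ], E[p, ], cfg), base, tolerance = 1e-10)
})

test_that("matched pairing beats mismatched pairing on separated embeddings", {
  cfg <- loss_config(temperature = 0.5)
  E <- diag(4)
  matched <- predann_loss(E, E, cfg)
  mismatched <- predann_loss(E[c(2, 3, 4, 1), ], E, cfg)
  expect_lt(matched, mismatched)
})

test_that("PredANN gradients obey the stop-gradient contract", {
  set.seed(25)
  B <- 4
  M <- matrix(rnorm(B * 5), B); E <- matrix(rnorm(B * 5), B)
  sg <- predann:::predann_loss_grad(M, E, loss_config(stop_gradient = TRUE))
  expect_true(all(sg$dM == 0))            # exactly zero, not just small
  expect_gt(max(abs(sg$dE)), 1e-4)
  free <- predann:::predann_loss_grad(M, E, loss_config(stop_gradient = FALSE))
  expect_gt(max(abs(free$dM)), 1e-4)
  # analytic gradients match finite differences
  cfgf <- loss_config(temperature = 0.3, stop_gradient = FALSE)
  gE <- numerical_grad(function(v) predann_loss(M, v, cfgf), E)
  gM <- numerical_grad(function(v) predann_loss(v, E, cfgf), M)
  fr <- predann:::predann_loss_grad(M, E, cfgf)
  expect_lt(max(abs(gE - fr$dE)), 1e-6)
  expect_lt(max(abs(gM - fr$dM)), 1e-6)
})

test_that("the total loss assembles the three components", {
  cfg <- loss_config(lambda_predann = 0.05)
  lb <- total_loss(1.2, 0.8, 2, cfg)
  expect_equal(lb$total, 1.2 + 0.8 + 0.1)
  # lambda = 0 reduces to the classification-only baseline
  lb0 <- total_loss(1.2, 0.8, 2, loss_config(lambda_predann = 0))
  expect_equal(lb0$total, 2.0)
  # doubling lambda doubles the predann contribution
  lb2 <- total_loss(1.2, 0.8, 2, loss_config(lambda_predann = 0.1))
  expect_equal(lb2$total - lb0$total, 2 * (lb$total - lb0$total))
  expect_error(total_loss(NaN, 0.8, 2, cfg), "non-finite")
  expect_error(loss_config(temperature = 0), "positive")
})
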