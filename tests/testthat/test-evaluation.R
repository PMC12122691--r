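test_that("window counts follow length - window + 1 at a 1-s stride", {
  fit <- tiny_fit(epochs = 1)
  fs <- fit$fs_eeg
  mk <- function(sec) matrix(rnorm(4 * sec * fs), 4)
  expect_identical(nrow(sliding_window_scores(fit, mk(5),
                                              true_label = 0)$scores), 3L)
  expect_identical(nrow(sliding_window_scores(fit, mk(7),
                                              true_label = 0)$scores), 5L)
  wp3 <- sliding_window_scores(fit, mk(3), true_label = 0)
  expect_identical(nrow(wp3$scores), 1L)
  # with a single window all aggregation methods coincide
  expect_identical(aggregate_mean(wp3)$predicted_class,
                   aggregate_max(wp3)$predicted_class)
  expect_identical(aggregate_mean(wp3)$predicted_class,
                   aggregate_majority(wp3)$predicted_class)
  expect_error(sliding_window_scores(fit, mk(2), true_label = 0), "shorter")
})

test_that("the worked example aggregates to class 8 (majority) and 7 (max)", {
  wp <- table8_fixture()
  votes <- max.col(wp$scores, ties.method = "first") - 1L
  expect_identical(votes, c(8L, 0L, 7L))       # per-window argmaxes
  maj <- aggregate_majority(wp)
  expect_identical(maj$predicted_class, 8L)    # tie broken by window 1
  mx <- aggregate_max(wp)
  expect_identical(mx$predicted_class, 7L)
  expect_equal(mx$per_class_evidence[8], 9.93e-1)  # class 7 evidence
  mn <- aggregate_mean(wp)
  expect_identical(mn$predicted_class, 8L)
  expect_equal(sum(mn$per_class_evidence), 1, tolerance = 0.005)
})

test_that("majority voting honours strict majorities and tie order", {
  sc <- function(v) {
    m <- matrix(0.01, length(v), 4); m[cbind(seq_along(v), v + 1)] <- 0.97
    window_predictions(m / rowSums(m))
  }
  expect_identical(aggregate_majority(sc(c(3, 3, 1)))$predicted_class, 3L)
  expect_identical(aggregate_majority(sc(c(1, 2, 2, 1, 3)))$predicted_class, 1L)
  expect_identical(aggregate_majority(sc(2))$predicted_class, 2L)
})

test_that("max aggregation equals brute-force search over all scores", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(6 * 5), 6); m <- m / rowSums(m)
    wp <- window_predictions(m)
    got <- aggregate_max(wp)$predicted_class
    best <- c(-1, -1)
    for (w in 1:nrow(m)) for (k in 1:ncol(m))
      if (m[w, k] > best[2]) best <- c(k - 1, m[w, k])
    expect_identical(got, as.integer(best[1]))
  }
})

test_that("mean aggregation is invariant to window order", {
  set.seed(32)
  m <- matrix(runif(5 * 4), 5); m <- m / rowSums(m)
  p <- sample(5)
  expect_equal(aggregate_mean(window_predictions(m)),
               aggregate_mean(window_predictions(m[p, ])))
})

test_that("exact McNemar p-values match binomial enumeration", {
  # identical arrays: no discordant pairs
  r <- mcnemar_test(c(1, 0, 1, 1), c(1, 0, 1, 1))
  expect_identical(r$p_value, 1)
  # hand-enumerated: n01 = 5, n10 = 1 -> 2 * (C(6,0)+C(6,1)) / 2^6
  a <- c(rep(0, 5), 1, rep(1, 4))
  b <- c(rep(1, 5), 0, rep(1, 4))
  expect_equal(mcnemar_test(a, b)$p_value, 0.21875)
  # symmetry under swapping the models
  expect_equal(mcnemar_test(b, a)$p_value, 0.21875)
  # full enumeration oracle for all discordant splits up to 20
  for (n in c(1, 2, 7, 13, 20)) {
    for (n01 in 0:n) {
      n10 <- n - n01
      a <- c(rep(0, n01), rep(1, n10))
      b <- c(rep(1, n01), rep(0, n10))
      k <- min(n01, n10)
      # oracle: sum the binomial pmf over both tails explicitly
      pmf <- choose(n, 0:n) / 2^n
      p_oracle <- min(1, sum(pmf[0:n <= k]) + sum(pmf[0:n >= n - k]))
      expect_equal(mcnemar_test(a, b)$p_value, p_oracle, tolerance = 1e-12)
    }
  }
})

test_that("chi-square McNemar agrees with the reference implementation", {
  a <- c(rep(1, 30), rep(0, 14), rep(1, 8), rep(0, 10))
  b <- c(rep(1, 30), rep(1, 14), rep(0, 8), rep(0, 10))
  got <- mcnemar_test(a, b, method = "chi2")
  ref <- mcnemar.test(table(factor(a, 0:1), factor(b, 0:1)), correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_error(mcnemar_test(a, b[1:3]), "equal")
})

test_that("accuracy breakdowns respect the partition identity", {
  set.seed(33)
  n <- 400
  df <- data.frame(true = sample(0:9, n, TRUE),
                   subject = sample(1:4, n, TRUE))
  df$song <- df$true
  df$predicted <- ifelse(runif(n) < 0.6, df$true, sample(0:9, n, TRUE))
  rep <- accuracy_report(df)
  w_song <- table(df$song)[names(rep$by_song)]
  expect_equal(sum(rep$by_song * w_song) / n, rep$overall,
               tolerance = 1e-12)
  w_sub <- table(df$subject)[names(rep$by_subject)]
  expect_equal(sum(rep$by_subject * w_sub) / n, rep$overall,
               tolerance = 1e-12)
  # all-correct gives 1 everywhere
  df2 <- df; df2$predicted <- df2$true
  rep2 <- accuracy_report(df2)
  expect_identical(rep2$overall, 1)
  expect_true(all(rep2$by_song == 1))
  expect_error(accuracy_report(df[c("predicted", "true")]), "missing")
})

test_that("uniform random guessing over 10 classes sits at chance", {
  set.seed(34)
  n <- 20000
  df <- data.frame(true = sample(0:9, n, TRUE),
                   predicted = sample(0:9, n, TRUE),
                   subject = 1)
  df$song <- df$true
  expect_equal(accuracy_report(df)$overall, 0.1, tolerance = 0.05)
})

test_that("chance level is the reciprocal of the class count", {
  expect_identical(chance_level(10), 0.1)
  expect_identical(chance_level(1), 1)
  expect_identical(chance_level(4), 0.25)
})
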