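test_that("robust scaling centres by median and scales by IQR", {
  r <- eeg_recording(matrix(c(0, 10, 20), nrow = 1))
  out <- robust_scale_channels(r)
  expect_equal(as.numeric(out$data), c(-1, 0, 1))

  # already-normalized channel (median 0, IQR 1) is unchanged
  x <- c(-0.5, 0, 0.5, -0.5, 0.5)   # median 0, IQR exactly 1
  out2 <- robust_scale_channels(eeg_recording(matrix(x, nrow = 1)))
  expect_equal(as.numeric(out2$data), x, tolerance = 1e-12)
})

test_that("zero-IQR channels are centred only and flagged", {
  r <- eeg_recording(rbind(c(5, 5, 5), c(0, 10, 20)))
  expect_warning(out <- robust_scale_channels(r), "zero IQR")
  expect_equal(as.numeric(out$data[1, ]), c(0, 0, 0))
  expect_equal(attr(out, "zero_iqr_channels"), 1L)
  expect_equal(as.numeric(out$data[2, ]), c(-1, 0, 1))
})

test_that("scaled channels have median 0 and IQR 1 (property)", {
  set.seed(42)
  for (rep in 1:5) {
    r <- eeg_recording(matrix(rnorm(6 * 200, mean = rnorm(1, sd = 10),
                                    sd = runif(1, 0.1, 8)), nrow = 6))
    out <- robust_scale_channels(r)$data
    meds <- apply(out, 1, median)
    iqrs <- apply(out, 1, IQR, type = 7)
    expect_true(all(abs(meds) < 1e-9))
    expect_true(all(abs(iqrs - 1) < 1e-9))
  }
})

test_that("clamping restricts values to +/- bound and is idempotent", {
  r <- eeg_recording(matrix(c(25, -25, 5, 19.9), nrow = 1))
  out <- clamp_values(r)
  expect_equal(as.numeric(out$data), c(20, -20, 5, 19.9))
  expect_equal(clamp_values(out)$data, out$data)  # idempotence
  expect_error(clamp_values(r, bound = -1), "positive")
})

test_that("240 s at 125 Hz yields eight 30-s excerpts that reconcatenate", {
  r <- eeg_recording(matrix(rnorm(2 * 250 * 125), nrow = 2), fs = 125,
                     song_id = 3)
  ex <- truncate_and_excerpt(r, total_seconds = 240, excerpt_seconds = 30)
  expect_length(ex, 8L)
  expect_true(all(vapply(ex, function(e) ncol(e$data), integer(1)) == 3750L))
  glued <- do.call(cbind, lapply(ex, `[[`, "data"))
  expect_identical(glued, r$data[, 1:(240 * 125)])  # bit-exact, 10 s dropped
  expect_equal(attr(ex[[5]], "excerpt_index"), 5L)
  expect_equal(as.numeric(ex[[1]]$song_id), 3)
})

test_that("truncation errors name the sample deficit", {
  r <- eeg_recording(matrix(0, 1, 100), fs = 125)
  expect_error(truncate_and_excerpt(r, 240, 30), "deficit 29900")
})

test_that("excerpt length equal to total duration returns the input", {
  r <- eeg_recording(matrix(rnorm(375), nrow = 1), fs = 125)
  ex <- truncate_and_excerpt(r, total_seconds = 3, excerpt_seconds = 3)
  expect_length(ex, 1L)
  expect_identical(ex[[1]]$data, r$data)
})

test_that("stratified split keeps per-class proportions and is seeded", {
  mk <- function(label) list(song_id = label)
  excerpts <- lapply(rep(0:4, each = 8), mk)
  sp <- stratified_split(excerpts, train_fraction = 0.75, seed = 7)
  expect_length(sp$train, 30L)       # 6 per class
  expect_length(sp$validation, 10L)  # 2 per class
  tr_lab <- vapply(sp$train, `[[`, numeric(1), "song_id")
  expect_true(all(table(tr_lab) == 6L))
  # union is the input, intersection empty
  expect_setequal(c(sp$train_idx, sp$validation_idx), seq_along(excerpts))
  expect_length(intersect(sp$train_idx, sp$validation_idx), 0L)
  # determinism
  sp2 <- stratified_split(excerpts, train_fraction = 0.75, seed = 7)
  expect_identical(sp$train_idx, sp2$train_idx)
  # 2 per class at fraction 0.5 -> 1/1
  sp3 <- stratified_split(lapply(rep(0:2, each = 2), mk),
                          train_fraction = 0.5, seed = 1)
  expect_true(all(table(vapply(sp3$train, `[[`, numeric(1),
                               "song_id")) == 1L))
})

test_that("a singleton class cannot be stratified", {
  excerpts <- lapply(c(0, 0, 1), function(l) list(song_id = l))
  expect_error(stratified_split(excerpts), "at least 2")
})

test_that("delay alignment shifts the EEG window by the right samples", {
  fs <- 125
  eeg <- eeg_recording(matrix(seq_len(10 * fs), nrow = 1), fs = fs,
                       song_id = 2)
  aud <- audio_stimulus(seq_len(10 * fs) / 1000, fs = fs, song_id = 2)
  # zero delay: identical time intervals
  s0 <- apply_delay(eeg, aud, delay_ms = 0, window_seconds = 2,
                    start_seconds = 1)
  expect_equal(s0$eeg[1, 1], 126)          # sample index 125 zero-based
  expect_equal(s0$audio[1], 126 / 1000)
  # 200 ms at 125 Hz -> 25-sample shift; 640 ms -> 80
  s200 <- apply_delay(eeg, aud, 200, 2, 1)
  expect_equal(s200$eeg[1, 1] - s0$eeg[1, 1], 25)
  s640 <- apply_delay(eeg, aud, 640, 2, 1)
  expect_equal(s640$eeg[1, 1] - s0$eeg[1, 1], 80)
  expect_equal(s200$label_eeg, 2)
  expect_error(apply_delay(eeg, aud, 200, 2, 8.5), "exceeds")
})

test_that("window extraction follows the count formula", {
  r <- matrix(rnorm(2 * 3750), nrow = 2)
  expect_length(extract_windows(r, 375, 375), 10L)
  expect_length(extract_windows(r, 375, 200), 17L)
  w <- extract_windows(r, 3750, 1)
  expect_length(w, 1L)
  expect_identical(w[[1]], r)
  expect_error(extract_windows(r, 4000, 1), "longer")
  # property over random shapes
  set.seed(3)
  for (i in 1:20) {
    n <- sample(50:500, 1); win <- sample(10:n, 1); st <- sample(1:60, 1)
    got <- length(extract_windows(matrix(0, 1, n), win, st))
    expect_identical(got, as.integer((n - win) %/% st + 1L))
    expect_identical(n_windows(n, win, st), as.integer((n - win) %/% st + 1L))
  }
})
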