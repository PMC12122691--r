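#' Robust-scale each EEG channel
#'
#' Normalizes every channel independently with the robust scaler: subtract
#' the channel median and divide by the channel interquartile range (IQR,
#' 75th minus 25th percentile, type-7 linear-interpolation quantiles).
#' Median/IQR statistics are insensitive to the sporadic large-amplitude
#' artifacts typical of EEG.  Channels whose IQR is zero (constant or
#' near-constant) are centred only and reported via a warning and the
#' `zero_iqr_channels` attribute.
#'
#' Statistics are fitted per channel per recording; no pooling across
#' recordings or subjects is performed.
#'
#' @param rec An [eeg_recording()].
#' @return The scaled recording; attribute `zero_iqr_channels` holds the
#'   indices of degenerate channels (integer(0) if none).
#' @export
#' @examples
#' r <- eeg_recording(matrix(c(0, 10, 20), nrow = 1))
#' robust_scale_channels(r)$data   # -1 0 1
robust_scale_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  if (ncol(x) < 2L)
    stop("robust scaling needs at least 2 samples per channel")
  med <- apply(x, 1L, stats::median)
  q <- apply(x, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
             type = 7)
  iqr <- q[2L, ] - q[1L, ]
  zero <- which(iqr == 0)
  scale <- ifelse(iqr == 0, 1, iqr)
  out <- (x - med) / scale
  if (length(zero))
    warning(sprintf("channel(s) %s have zero IQR; centred only",
                    paste(zero, collapse = ", ")))
  res <- eeg_recording(out, rec$fs, rec$subject_id, rec$song_id)
  attr(res, "zero_iqr_channels") <- as.integer(zero)
  res
}

#' Clamp EEG amplitudes to a symmetric range
#'
#' Applied after robust scaling, clamping restricts values to
#' `[-bound, +bound]` (default +/- 20) so that residual outliers cannot
#' destabilize training.  Values already inside the range are unchanged;
#' the operation is idempotent.
#'
#' @param rec An [eeg_recording()].
#' @param bound Positive clamp bound (default 20).
#' @return The clamped recording.
#' @export
clamp_values <- function(rec, bound = 20) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0)
    stop("`bound` must be a positive scalar")
  out <- pmin(pmax(rec$data, -bound), bound)
  eeg_recording(out, rec$fs, rec$subject_id, rec$song_id)
}

#' Truncate a recording and split it into fixed-length excerpts
#'
#' Truncates the recording to `total_seconds` (default 240 s, i.e. the
#' shared 4-minute duration) and partitions it into contiguous,
#' non-overlapping excerpts of `excerpt_seconds` (default 30 s).  The
#' excerpts concatenate exactly to the truncated signal.
#'
#' @param rec An [eeg_recording()].
#' @param total_seconds Duration kept from the start of the recording.
#' @param excerpt_seconds Length of each excerpt; must divide
#'   `total_seconds` to an integer number of excerpts.
#' @return List of [eeg_recording()] excerpts in temporal order; each
#'   carries an `excerpt_index` attribute (1-based position).
#' @export
truncate_and_excerpt <- function(rec, total_seconds = 240,
                                 excerpt_seconds = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_total <- round(total_seconds * rec$fs)
  n_exc <- round(excerpt_seconds * rec$fs)
  if (ncol(rec$data) < n_total)
    stop(sprintf(
      "recording too short: %d samples available, %d required (deficit %d)",
      ncol(rec$data), n_total, n_total - ncol(rec$data)))
  k <- total_seconds / excerpt_seconds
  if (abs(k - round(k)) > 1e-9)
    stop("`excerpt_seconds` must divide `total_seconds` evenly")
  k <- round(k)
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * n_exc + 1L):(i * n_exc)
    e <- eeg_recording(rec$data[, idx, drop = FALSE], rec$fs,
                       rec$subject_id, rec$song_id)
    attr(e, "excerpt_index") <- i
    e
  })
}

#' Stratified train/validation split of labelled excerpts
#'
#' Splits a list of labelled units (anything carrying a `song_id`, e.g.
#' excerpt recordings) into train and validation sets so that each class
#' contributes `train_fraction` of its units to training (rounded to the
#' nearest integer, with both sides kept non-empty).  Assignment is a pure
#' function of `seed` and leaves the caller's RNG untouched.
#'
#' @param excerpts List of objects with a `song_id` field, or a plain label
#'   vector via `labels`.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.75, the 75:25 split).
#' @param seed Integer seed controlling the within-class shuffle.
#' @param labels Optional explicit label vector overriding `song_id`
#'   extraction.
#' @return List with elements `train`, `validation` (sub-lists of the
#'   input) and `train_idx`, `validation_idx` (indices into the input).
#' @export
stratified_split <- function(excerpts, train_fraction = 0.75, seed = 0,
                             labels = NULL) {
  if (is.null(labels))
    labels <- vapply(excerpts, function(e) as.numeric(e$song_id), numeric(1))
  n <- length(labels)
  if (n != length(excerpts)) stop("labels/excerpts length mismatch")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 excerpts to stratify; offending class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == as.numeric(cl))
    n_c <- length(idx)
    n_train <- round(train_fraction * n_c)
    n_train <- min(max(n_train, 1L), n_c - 1L)  # both sides non-empty
    perm <- with_seed(seed + as.numeric(cl), sample(idx))
    train_idx <- c(train_idx, perm[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n), train_idx)
  list(train = excerpts[train_idx], validation = excerpts[val_idx],
       train_idx = train_idx, validation_idx = val_idx)
}

#' Cut a delay-aligned paired segment
#'
#' Extracts an audio window covering `[start, start + window)` seconds of
#' the stimulus and the EEG window covering the same interval shifted
#' later by `delay_ms`, accounting for the latency with which auditory
#' stimuli are encoded in cortex.  The EEG start index is
#' `round((start + delay_ms/1000) * fs_eeg)` (zero-based sample offsets,
#' half-open windows, rounding to the nearest sample).
#'
#' @param eeg An [eeg_recording()].
#' @param audio An [audio_stimulus()].
#' @param delay_ms Stimulus-to-EEG latency in milliseconds (>= 0).
#' @param window_seconds Window length in seconds.
#' @param start_seconds Audio window start in seconds (>= 0).
#' @return A [paired_segment()].
#' @export
apply_delay <- function(eeg, audio, delay_ms, window_seconds,
                        start_seconds = 0) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(audio, "audio_stimulus"))
  if (delay_ms < 0) stop("`delay_ms` must be non-negative")
  a0 <- round(start_seconds * audio$fs)           # zero-based
  wa <- round(window_seconds * audio$fs)
  if (a0 + wa > length(audio$waveform))
    stop("audio window exceeds stimulus length")
  e0 <- round((start_seconds + delay_ms / 1000) * eeg$fs)
  we <- round(window_seconds * eeg$fs)
  if (e0 + we > ncol(eeg$data))
    stop(sprintf(
      "delayed EEG window [%d, %d) exceeds recording length %d",
      e0, e0 + we, ncol(eeg$data)))
  paired_segment(
    eeg = eeg$data[, (e0 + 1L):(e0 + we), drop = FALSE],
    audio = audio$waveform[(a0 + 1L):(a0 + wa)],
    label_eeg = eeg$song_id, label_music = audio$song_id,
    delay_ms = delay_ms, subject_id = eeg$subject_id,
    strict = FALSE)
}

#' Extract strided windows from a recording
#'
#' Returns all windows of `window_samples` samples starting every
#' `stride_samples` samples, in temporal order:
#' `floor((n_samples - window_samples) / stride) + 1` windows.  Training
#' uses a coarse stride (200 samples) for efficiency; evaluation uses
#' stride 1 to score every available data point.
#'
#' @param rec An [eeg_recording()] or a plain numeric matrix
#'   (channels x samples).
#' @param window_samples Window length in samples.
#' @param stride_samples Stride in samples (>= 1).
#' @return List of numeric matrices (channels x window_samples).
#' @export
extract_windows <- function(rec, window_samples, stride_samples) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  n <- ncol(x)
  if (window_samples > n)
    stop(sprintf("window (%d) longer than recording (%d)", window_samples, n))
  if (stride_samples < 1L) stop("`stride_samples` must be >= 1")
  starts <- seq.int(0L, n - window_samples, by = stride_samples)
  lapply(starts, function(s) x[, (s + 1L):(s + window_samples), drop = FALSE])
}

#' Number of strided windows
#'
#' Closed form for the count returned by [extract_windows()].
#' @param n_samples,window_samples,stride_samples Integers.
#' @return `floor((n_samples - window_samples) / stride) + 1`.
#' @export
n_windows <- function(n_samples, window_samples, stride_samples) {
  if (window_samples > n_samples) return(0L)
  as.integer((n_samples - window_samples) %/% stride_samples + 1L)
}

#' Polyphase-style resampling of a recording
#'
#' Optional utility for raw high-rate input (e.g. 1000 Hz EEG) that must
#' be brought to the 125 Hz modelling rate.  Uses FFT-based resampling
#' per channel; the pipeline otherwise assumes inputs already at target
#' rates.
#'
#' @param rec An [eeg_recording()].
#' @param fs_out Target sampling rate in Hz.
#' @return The resampled recording at `fs_out`.
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_out == rec$fs) return(rec)
  n_in <- ncol(rec$data)
  n_out <- round(n_in * fs_out / rec$fs)
  out <- t(apply(rec$data, 1L, function(ch) {
    stats::spline(x = seq_len(n_in), y = ch,
                  xout = seq(1, n_in, length.out = n_out))$y
  }))
  eeg_recording(out, fs_out, rec$subject_id, rec$song_id)
}

#' Full preprocessing of one recording
#'
#' Convenience composition of the fixed pipeline order: robust scaling
#' first, then clamping, then truncation into excerpts.
#'
#' @inheritParams robust_scale_channels
#' @inheritParams clamp_values
#' @inheritParams truncate_and_excerpt
#' @return List of preprocessed excerpt recordings.
#' @export
preprocess_recording <- function(rec, bound = 20, total_seconds = 240,
                                 excerpt_seconds = 30) {
  rec <- robust_scale_channels(rec)
  rec <- clamp_values(rec, bound)
  truncate_and_excerpt(rec, total_seconds, excerpt_seconds)
}
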